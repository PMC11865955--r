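#' Allometric scaling of vessel dimensions
#'
#' Scales a literature vessel dimension (length or radius) to a patient of a
#' given body weight by the allometric power law
#' `L2 = L1 * (W1 / W2)^exponent`.
#'
#' @param L1 literature dimension (cm), positive.
#' @param W1 literature body weight (kg), positive.
#' @param W2 patient body weight (kg), positive.
#' @param exponent allometric exponent; default 0.35.
#' @return scaled dimension (cm).
#' @examples
#' allometric_scale(10, 70, 35) # longer vessel for the lighter subject
#' @export
allometric_scale <- function(L1, W1, W2, exponent = 0.35) {
  for (nm in c("L1", "W1", "W2")) {
    val <- get(nm)
    if (!is.numeric(val) || any(!is.finite(val)) || any(val <= 0)) {
      abort(sprintf("`%s` must be a positive finite number.", nm))
    }
  }
  L1 * (W1 / W2)^exponent
}

#' Assemble and validate a vessel network
#'
#' Builds a rooted directed tree from a vessel table and an edge list. The
#' terminal flag of each vessel is derived from the edge list (a vessel is
#' terminal iff it has no children). Validation rejects duplicate ids, orphan
#' vessels, multiple parents, cycles and junctions with more than two children.
#'
#' @param vessels data frame with columns `id`, `length_cm`, `r_in_cm`,
#'   `r_out_cm`, and optionally `name`, `group_large`, `group_small`,
#'   `r_min_cm`.
#' @param edges data frame with columns `parent`, `child` (vessel ids); may
#'   have zero rows for a single-vessel network.
#' @return an object of class `pt_network`: a list with tibbles `vessels` and
#'   `edges` and the integer `root_id`.
#' @export
build_network <- function(vessels, edges = NULL) {
  vessels <- as_tibble(vessels)
  if (is.null(edges)) edges <- tibble(parent = integer(), child = integer())
  edges <- as_tibble(edges)
  req <- c("id", "length_cm", "r_in_cm", "r_out_cm")
  miss <- setdiff(req, names(vessels))
  if (length(miss)) abort(paste0("vessel table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(vessels$id)) abort("duplicate vessel id in vessel table")
  if (any(vessels$length_cm <= 0) || any(vessels$r_in_cm <= 0) ||
      any(vessels$r_out_cm <= 0)) {
    abort("vessel lengths and radii must be positive")
  }
  if (nrow(edges)) {
    bad <- setdiff(c(edges$parent, edges$child), vessels$id)
    if (length(bad)) abort(paste0("edge list references unknown vessel id(s): ",
                                  paste(bad, collapse = ", ")))
    if (anyDuplicated(edges$child)) {
      abort("a vessel has multiple parents; the network must be a tree")
    }
    nkids <- table(edges$parent)
    if (any(nkids > 2)) abort("junctions may have at most two children")
  }
  has_parent <- vessels$id %in% edges$child
  roots <- vessels$id[!has_parent]
  if (length(roots) != 1) {
    abort(sprintf("network must have exactly one root vessel, found %d",
                  length(roots)))
  }
  root_id <- roots[[1]]
  # reachability walk from the root detects cycles / disconnected components
  seen <- root_id
  frontier <- root_id
  while (length(frontier)) {
    kids <- edges$child[edges$parent %in% frontier]
    if (any(kids %in% seen)) abort("cycle detected in edge list")
    seen <- c(seen, kids)
    frontier <- kids
  }
  if (length(seen) != nrow(vessels)) {
    abort("orphan vessel(s): not all vessels are reachable from the root")
  }
  vessels$terminal <- !(vessels$id %in% edges$parent)
  if (!"name" %in% names(vessels)) vessels$name <- paste0("vessel ", vessels$id)
  if (!"r_min_cm" %in% names(vessels)) vessels$r_min_cm <- NA_real_
  term_rmin <- vessels$r_min_cm[vessels$terminal]
  if (any(!is.na(term_rmin) &
          (term_rmin <= 0 |
           term_rmin >= vessels$r_out_cm[vessels$terminal]))) {
    abort("terminal r_min_cm must be positive and smaller than r_out_cm")
  }
  structure(list(vessels = vessels, edges = edges, root_id = root_id),
            class = "pt_network")
}

# group membership of the canonical 17-vessel network
large_vessel_groups <- function() {
  list(`1` = c(1, 2, 3, 4, 7), `2` = c(10, 11, 14, 15),
       `3` = c(5, 12, 13), `4` = c(6, 8, 9, 16, 17))
}

small_vessel_groups <- function() {
  list(`1` = 7, `2` = c(10, 14, 15), `3` = c(12, 13), `4` = c(8, 9, 16, 17))
}

group_lookup <- function(groups) {
  ids <- unlist(groups, use.names = FALSE)
  g <- rep(as.integer(names(groups)), lengths(groups))
  setNames(g, ids)
}

canonical_dimensions <- function(cohort) {
  # mean length / inlet radius / outlet radius per vessel, by cohort
  dorv <- tibble(
    id   = 1:17,
    name = c("Asc aorta", "AA I", "Innom", "AA II", "LCC", "L Subcl",
             "Desc aorta", "L Brachial", "L Vertebral", "R Subcl", "RCC",
             "L Ext C", "L Int C", "R Int C", "R Ext C", "R Brachial",
             "R Vertebral"),
    length_cm = c(3.8, 1.6, 4.3, 2.5, 20.1, 3.3, 35.1, 20.1, 14.3, 3.3,
                  17.1, 17.1, 17.0, 17.0, 17.1, 20.1, 14.3),
    r_in_cm   = c(1.18, 1.04, 0.53, 1.00, 0.32, 0.36, 0.87, 0.31, 0.24,
                  0.36, 0.32, 0.27, 0.21, 0.21, 0.27, 0.21, 0.24),
    r_out_cm  = c(1.04, 1.00, 0.53, 0.87, 0.31, 0.34, 0.59, 0.26, 0.23,
                  0.34, 0.30, 0.24, 0.17, 0.17, 0.24, 0.21, 0.23)
  )
  hlhs <- dorv
  hlhs$length_cm <- c(2.9, 1.5, 3.1, 1.5, 20.1, 3.5, 35.1, 20.1, 14.3, 3.5,
                      17.1, 17.1, 17.0, 17.0, 17.1, 20.1, 14.3)
  hlhs$r_in_cm   <- c(1.36, 1.52, 0.54, 1.31, 0.30, 0.21, 0.74, 0.30, 0.24,
                      0.21, 0.34, 0.28, 0.24, 0.24, 0.28, 0.24, 0.24)
  hlhs$r_out_cm  <- c(1.52, 1.31, 0.54, 0.74, 0.27, 0.28, 0.55, 0.28, 0.22,
                      0.28, 0.31, 0.26, 0.26, 0.23, 0.26, 0.23, 0.22)
  if (cohort == "DORV") dorv else hlhs
}

canonical_edges <- function() {
  tibble(parent = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 10, 10, 11, 11),
         child  = c(2, 3, 4, 5, 10, 11, 6, 7, 12, 13, 8, 9, 16, 17, 14, 15))
}

#' Canonical 17-vessel aortic-arch network
#'
#' Assembles the standard head-and-neck/aortic-arch topology used for the
#' single-ventricle cohorts: ascending aorta, two aortic-arch segments,
#' descending aorta, innominate, carotid, subclavian, brachial and vertebral
#' vessels (17 vessels, 9 terminal). Dimensions are cohort means; stiffness
#' group labels and terminal minimum radii are attached.
#'
#' The structured-tree termination radius is 0.001 cm (arteriolar level) for
#' every terminal vessel except the descending aorta, which is truncated at a
#' larger radius and uses 0.01 cm.
#'
#' @param cohort `"DORV"` (native aorta) or `"HLHS"` (reconstructed aorta).
#' @return a `pt_network`.
#' @examples
#' net <- canonical_network("DORV")
#' sum(net$vessels$terminal)
#' @export
canonical_network <- function(cohort = c("DORV", "HLHS")) {
  cohort <- match.arg(cohort)
  v <- canonical_dimensions(cohort)
  gl <- group_lookup(large_vessel_groups())
  gs <- group_lookup(small_vessel_groups())
  v$group_large <- unname(gl[as.character(v$id)])
  v$group_small <- unname(gs[as.character(v$id)])
  v$r_min_cm <- ifelse(v$id == 7, 0.01,
                       ifelse(v$id %in% terminal_ids_canonical(), 0.001,
                              NA_real_))
  build_network(v, canonical_edges())
}

terminal_ids_canonical <- function() c(7, 8, 9, 12, 13, 14, 15, 16, 17)

#' Extract a rooted subnetwork
#'
#' Keeps the listed vessels (which must form a rooted subtree) and re-derives
#' terminal flags. Vessels that become terminal receive the supplied
#' structured-tree termination radius.
#'
#' @param net a `pt_network`.
#' @param ids vessel ids to keep.
#' @param r_min_new termination radius (cm) assigned to newly terminal vessels.
#' @return a `pt_network`.
#' @export
subnetwork <- function(net, ids, r_min_new = 0.01) {
  stopifnot(inherits(net, "pt_network"))
  v <- dplyr::filter(net$vessels, .data$id %in% ids)
  e <- dplyr::filter(net$edges, .data$parent %in% ids & .data$child %in% ids)
  was_terminal <- v$id[v$terminal %in% TRUE]
  v$terminal <- NULL
  sub <- build_network(v, e)
  new_term <- setdiff(sub$vessels$id[sub$vessels$terminal], was_terminal)
  sub$vessels$r_min_cm[sub$vessels$id %in% new_term] <- r_min_new
  sub
}

#' Unstressed radius profile along a vessel
#'
#' The solver needs a continuous unstressed radius r0(x); only the inlet and
#' outlet radii are measured. By default an exponential taper
#' `r0(x) = r_in * (r_out/r_in)^(x/L)` is used (smooth, positive, matches both
#' ends); a linear taper is available.
#'
#' @param vessel one row of a network's vessel table (list or data frame row).
#' @param x positions along the vessel, in \[0, L\] (cm).
#' @param taper `"exponential"` or `"linear"`.
#' @return radii (cm) at `x`.
#' @export
vessel_radius <- function(vessel, x, taper = c("exponential", "linear")) {
  taper <- match.arg(taper)
  L <- vessel$length_cm; ri <- vessel$r_in_cm; ro <- vessel$r_out_cm
  if (taper == "exponential") ri * (ro / ri)^(x / L)
  else ri + (ro - ri) * x / L
}

#' Write / read a network as a CSV pair
#'
#' `write_network()` writes `vessels.csv` and `edges.csv` into a directory;
#' `read_network()` reads them back and re-validates. The round trip is the
#' identity on the network.
#'
#' @param net a `pt_network`.
#' @param dir directory path.
#' @return `read_network()` returns a `pt_network`; `write_network()` returns
#'   `dir` invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "pt_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- c("id", "name", "length_cm", "r_in_cm", "r_out_cm",
            "group_large", "group_small", "terminal", "r_min_cm")
  v <- net$vessels
  for (cc in setdiff(cols, names(v))) v[[cc]] <- NA
  readr::write_csv(v[cols], file.path(dir, "vessels.csv"))
  readr::write_csv(net$edges, file.path(dir, "edges.csv"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  v <- readr::read_csv(file.path(dir, "vessels.csv"),
                       show_col_types = FALSE)
  e <- readr::read_csv(file.path(dir, "edges.csv"), show_col_types = FALSE)
  v$terminal <- NULL
  build_network(v, e)
}

#' @export
print.pt_network <- function(x, ...) {
  cat(sprintf("<pt_network> %d vessels, %d terminal, root = vessel %d\n",
              nrow(x$vessels), sum(x$vessels$terminal), x$root_id))
  print(x$vessels, n = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a vessel network
#'
#' @param x a `pt_network`.
#' @param ... unused.
#' @return the vessel table as a tibble, with a `parent` column joined on.
#' @export
tidy.pt_network <- function(x, ...) {
  parent_of <- setNames(x$edges$parent, x$edges$child)
  dplyr::mutate(x$vessels,
                parent = unname(parent_of[as.character(.data$id)]))
}

# ordered traversal helpers used by the solver
network_children <- function(net, id) net$edges$child[net$edges$parent == id]
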