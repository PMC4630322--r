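#' Radial region analysis of a tumor snapshot
#'
#' Bins cells into concentric shells around the population centroid and
#' labels each shell by its state composition: pure (>= \code{pure_threshold}
#' of one state) necrotic / quiescent / proliferating shells, the mixed
#' necrotic-quiescent annulus, or generic mixtures. Boundary radii are read
#' off the label transitions: \code{U_N} closes the pure necrotic core,
#' \code{U_Q1} the mixed necrotic-quiescent annulus, \code{U_Q2} the pure
#' quiescent annulus, and \code{U_T} encloses every cell. Absent regions are
#' reported as NA.
#'
#' @param cells Snapshot population (>= 1 cell).
#' @param shell_width Shell width (cm); default one cell diameter.
#' @param pure_threshold Composition fraction defining a pure shell.
#' @return Object of class \code{"ava_regions"}: \code{centroid},
#'   \code{shells} (data frame with per-shell composition and label) and
#'   \code{radii} (named list U_N, U_Q1, U_Q2, U_T).
#' @export
classify_regions <- function(cells, shell_width = 0.002, pure_threshold = 0.95) {
  if (!nrow(cells)) stop("region analysis needs at least one cell")
  pos <- cell_positions(cells)
  centroid <- colMeans(pos)
  dist <- sqrt(rowSums(sweep(pos, 2, centroid)^2))
  u_t <- max(dist + cells$radius)
  if (nrow(cells) == 1L) {
    return(structure(list(centroid = centroid,
                          shells = data.frame(),
                          radii = list(U_N = NA_real_, U_Q1 = NA_real_,
                                       U_Q2 = NA_real_, U_T = u_t)),
                     class = "ava_regions"))
  }
  nshell <- max(1L, ceiling(max(dist) / shell_width))
  shell <- pmin(floor(dist / shell_width), nshell - 1L) + 1L
  lev <- cell_states()
  comp <- t(vapply(seq_len(nshell), function(s) {
    st <- cells$state[shell == s]
    if (!length(st)) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(table(factor(st, levels = lev)) / length(st))
  }, numeric(3)))
  colnames(comp) <- lev
  label <- apply(comp, 1, function(fr) {
    if (anyNA(fr)) return("empty")
    if (fr["necrotic"] >= pure_threshold) return("necrotic")
    if (fr["quiescent"] >= pure_threshold) return("quiescent")
    if (fr["proliferating"] >= pure_threshold) return("proliferating")
    if (fr["proliferating"] < 1 - pure_threshold) return("mixed_necrotic_quiescent")
    if (fr["necrotic"] < 1 - pure_threshold) return("mixed_proliferating_quiescent")
    "mixed"
  })
  outer <- seq_len(nshell) * shell_width
  shells <- data.frame(shell = seq_len(nshell),
                       r_inner = outer - shell_width, r_outer = outer,
                       n = as.integer(tabulate(shell, nshell)),
                       comp, label = label)

  # walk outward: core -> mixed N/Q annulus -> pure quiescent annulus
  run_end <- function(labels, want, from) {
    i <- from; last <- NA_integer_
    while (i <= length(labels)) {
      if (labels[i] %in% want) last <- i
      else if (labels[i] != "empty") break
      i <- i + 1L
    }
    last
  }
  i_n <- run_end(label, "necrotic", 1L)
  u_n <- if (is.na(i_n)) NA_real_ else outer[i_n]
  i_a <- run_end(label, "mixed_necrotic_quiescent",
                 if (is.na(i_n)) 1L else i_n + 1L)
  u_q1 <- if (is.na(i_a)) NA_real_ else outer[i_a]
  i_q <- run_end(label, "quiescent",
                 max(i_n, i_a, 0L, na.rm = TRUE) + 1L)
  u_q2 <- if (is.na(i_q)) NA_real_ else outer[i_q]
  structure(list(centroid = centroid, shells = shells,
                 radii = list(U_N = u_n, U_Q1 = u_q1, U_Q2 = u_q2, U_T = u_t)),
            class = "ava_regions")
}

#' @export
print.ava_regions <- function(x, ...) {
  r <- x$radii
  cat(sprintf("Tumor region report: U_N = %s, U_Q1 = %s, U_Q2 = %s, U_T = %s cm\n",
              format(r$U_N), format(r$U_Q1), format(r$U_Q2), format(r$U_T)))
  if (nrow(x$shells)) {
    runs <- rle(x$shells$label)
    cat("Shell labels (inside out):",
        paste(sprintf("%s x%d", runs$values, runs$lengths), collapse = ", "), "\n")
  }
  invisible(x)
}

# minimal union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# connected-component labels under center-distance adjacency
.components <- function(pos, rad, linkage) {
  m <- nrow(pos)
  parent <- seq_len(m)
  if (m > 1L) {
    pr <- neighbor_pairs(pos, linkage * 2 * max(rad))
    if (length(pr$i)) {
      keep <- pr$d <= linkage * (rad[pr$i] + rad[pr$j])
      for (k in which(keep)) {
        ri <- .uf_find(parent, pr$i[k]); rj <- .uf_find(parent, pr$j[k])
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(m), function(i) .uf_find(parent, i), integer(1))
}

#' Count spatially separate tumor islands
#'
#' Connected components of living (proliferating or quiescent) cells under
#' center-distance adjacency. A second island appears when a stem-cell spawn
#' grows into a satellite tumor detached from the primary.
#'
#' @param cells Snapshot population.
#' @param linkage Adjacency multiple of summed radii.
#' @param min_size Minimum component size to count as an island.
#' @return Data frame with one row per island: \code{island}, \code{size},
#'   \code{x}, \code{y} (component centroid), largest first.
#' @export
find_tumor_islands <- function(cells, linkage = 2, min_size = 10L) {
  living <- which(cells$state != "necrotic")
  empty <- data.frame(island = integer(), size = integer(),
                      x = numeric(), y = numeric())
  if (!length(living)) return(empty)
  pos <- cell_positions(cells)[living, , drop = FALSE]
  lab <- .components(pos, cells$radius[living], linkage)
  comps <- split(seq_along(living), lab)
  comps <- comps[lengths(comps) >= min_size]
  if (!length(comps)) return(empty)
  out <- data.frame(island = seq_along(comps),
                    size = lengths(comps),
                    x = vapply(comps, function(ix) mean(pos[ix, 1]), numeric(1)),
                    y = vapply(comps, function(ix) mean(pos[ix, 2]), numeric(1)))
  out <- out[order(-out$size), ]
  out$island <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Necrotic agglomerations outside the core
#'
#' Connected components of necrotic cells under center-distance adjacency
#' (<= \code{linkage} times the summed radii). The contiguous core component
#' covering the population centroid is excluded; the remaining components are
#' the satellite agglomerations scattered through the mixed annulus.
#'
#' @param cells Snapshot population.
#' @param linkage Adjacency multiple of summed radii.
#' @return List of class \code{"ava_agglomerations"}: \code{count},
#'   \code{sizes}, \code{members} (list of cell-id vectors) and
#'   \code{core_ids} (ids of the excluded core component, possibly empty).
#' @export
find_agglomerations <- function(cells, linkage = 1.2) {
  nec <- which(cells$state == "necrotic")
  if (!length(nec))
    return(structure(list(count = 0L, sizes = integer(), members = list(),
                          core_ids = integer()),
                     class = "ava_agglomerations"))
  pos_all <- cell_positions(cells)
  centroid <- colMeans(pos_all)
  pos <- pos_all[nec, , drop = FALSE]
  rad <- cells$radius[nec]
  m <- length(nec)
  root <- .components(pos, rad, linkage)
  comps <- split(seq_len(m), root)
  # core component: contains a member overlapping the centroid
  dcent <- sqrt(rowSums(sweep(pos, 2, centroid)^2))
  is_core <- vapply(comps, function(ix) any(dcent[ix] <= linkage * 2 * rad[ix]),
                    logical(1))
  core_ids <- if (any(is_core)) cells$id[nec[unlist(comps[is_core])]] else integer()
  sat <- comps[!is_core]
  members <- lapply(sat, function(ix) cells$id[nec[ix]])
  sizes <- lengths(members)
  ord <- order(-sizes)
  structure(list(count = length(sat), sizes = unname(sizes[ord]),
                 members = unname(members[ord]), core_ids = core_ids),
            class = "ava_agglomerations")
}

#' @export
print.ava_agglomerations <- function(x, ...) {
  cat(sprintf("%d necrotic agglomeration(s) outside the core", x$count))
  if (x$count) cat(" with sizes", paste(x$sizes, collapse = ", "))
  cat("\n")
  invisible(x)
}

# square-lattice cell packing of a disk
.lattice_disk <- function(center, r_disk, spacing, radius, dim = 2L) {
  ax <- seq(-r_disk, r_disk, by = spacing)
  g <- as.matrix(do.call(expand.grid, rep(list(ax), dim)))
  g <- g[rowSums(g^2) <= r_disk^2, , drop = FALSE]
  sweep(g, 2, center, "+")
}

#' Generate synthetic tumor snapshots with known ground truth
#'
#' Deterministic (seeded) synthetic cell configurations for exercising the
#' morphology analysis: \code{layered_tumor} (pure necrotic core, quiescent
#' annulus, proliferating rim at prescribed radii), \code{random_gas}
#' (uniform random cells in the domain), \code{planted_clusters} (a quiescent
#' lattice sea with k compact necrotic clusters planted on a ring) and
#' \code{two_tumors} (a main layered tumor plus a smaller satellite, the
#' cancer-stem-cell secondary-tumor scenario).
#'
#' @param kind Fixture kind.
#' @param params Named list of kind-specific parameters. Common:
#'   \code{center}, \code{cell_radius} (default 0.001 cm). layered_tumor /
#'   two_tumors: \code{r_n}, \code{r_q}, \code{r_t} (region radii, cm);
#'   two_tumors adds \code{offset} and \code{satellite_r}. random_gas:
#'   \code{n}, \code{r_disk}. planted_clusters: \code{k},
#'   \code{cluster_radius}, \code{sea_radius}.
#' @param seed RNG seed (only \code{random_gas} draws random numbers).
#' @return List: \code{cells} (an \code{"ava_cells"} frame) and \code{truth}
#'   (kind-specific ground-truth description).
#' @export
generate_fixture <- function(kind = c("layered_tumor", "random_gas",
                                      "planted_clusters", "two_tumors"),
                             params = list(), seed = NULL) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown fixture kind: ", kind[1]))
  if (!is.null(seed)) set.seed(seed)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  rc <- p("cell_radius", 0.001)
  ctr <- p("center", c(0.2, 0.2))
  spacing <- 2 * rc
  build <- function(pos, state, health) {
    make_cells(x = pos[, 1], y = pos[, 2],
               z = if (ncol(pos) == 3) pos[, 3] else NULL,
               radius = rc, state = state, health = health,
               necrosis_time = ifelse(state == "necrotic", 0L, NA_integer_))
  }
  if (kind == "layered_tumor" || kind == "two_tumors") {
    r_n <- p("r_n", 0.01); r_q <- p("r_q", 0.02); r_t <- p("r_t", 0.03)
    pos <- .lattice_disk(ctr, r_t, spacing, rc, length(ctr))
    d <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
    state <- ifelse(d <= r_n, "necrotic",
             ifelse(d <= r_q, "quiescent", "proliferating"))
    health <- ifelse(state == "necrotic", 0.3, ifelse(state == "quiescent", 1, 2))
    truth <- list(r_n = r_n, r_q = r_q, r_t = r_t, center = ctr)
    if (kind == "two_tumors") {
      off <- p("offset", c(0.09, 0))
      sr <- p("satellite_r", 0.012)
      ctr2 <- ctr + off
      pos2 <- .lattice_disk(ctr2, sr, spacing, rc, length(ctr))
      cells <- build(rbind(pos, pos2),
                     c(state, rep("proliferating", nrow(pos2))),
                     c(health, rep(2, nrow(pos2))))
      cells$id <- seq_len(nrow(cells))
      truth$satellite <- list(center = ctr2, r = sr, n = nrow(pos2))
      return(list(cells = cells, truth = truth))
    }
    return(list(cells = build(pos, state, health), truth = truth))
  }
  if (kind == "random_gas") {
    n <- p("n", 100L); r_disk <- p("r_disk", 0.05)
    if (n == 0L)
      return(list(cells = make_cells(), truth = list(n = 0L)))
    u <- stats::runif(n); th <- stats::runif(n, 0, 2 * pi)
    r <- r_disk * sqrt(u)
    pos <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
    return(list(cells = build(pos, "quiescent", 1), truth = list(n = n)))
  }
  # planted_clusters
  k <- p("k", 3L)
  sea_r <- p("sea_radius", 0.05)
  cl_r <- p("cluster_radius", 0.006)
  pos <- .lattice_disk(ctr, sea_r, spacing, rc, length(ctr))
  state <- rep("quiescent", nrow(pos))
  ring <- sea_r * 0.6
  centers <- lapply(seq_len(k), function(i) {
    th <- 2 * pi * (i - 1) / k
    ctr + c(cos(th), sin(th)) * ring
  })
  membership <- vector("list", k)
  for (i in seq_len(k)) {
    d <- sqrt(rowSums(sweep(pos, 2, centers[[i]])^2))
    membership[[i]] <- which(d <= cl_r)
    state[membership[[i]]] <- "necrotic"
  }
  cells <- build(pos, state, ifelse(state == "necrotic", 0.3, 1))
  list(cells = cells,
       truth = list(k = k, centers = centers,
                    members = lapply(membership, function(ix) cells$id[ix])))
}

#' Write/read a cell snapshot CSV
#'
#' Columns: iteration, id, x, y (z if 3-D), radius, state, health,
#' generation, mutations.
#'
#' @param cells The population.
#' @param file Path.
#' @param iteration Iteration stamp for the snapshot.
#' @return \code{read_cells_csv}: an \code{"ava_cells"} frame (with an
#'   \code{iteration} attribute); \code{write_cells_csv}: the path,
#'   invisibly.
#' @export
write_cells_csv <- function(cells, file, iteration = 0L) {
  df <- as.data.frame(cells)
  df <- cbind(iteration = iteration, df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  it <- if ("iteration" %in% names(df)) df$iteration[1] else 0L
  df$iteration <- NULL
  if (!"necrosis_time" %in% names(df)) df$necrosis_time <- NA_integer_
  class(df) <- c("ava_cells", "data.frame")
  attr(df, "iteration") <- it
  df
}
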