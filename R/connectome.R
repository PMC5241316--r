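#' Area table of the modelled cortex
#'
#' The full architecture models twelve left-hemispheric areas as two
#' six-area systems: the perisylvian ("language") stream from primary
#' auditory cortex to inferior primary motor cortex, and the extrasylvian
#' ("semantic") stream from primary visual to dorsolateral primary motor
#' cortex. The miniature scale keeps one primary, one hub-adjacent and one
#' motor end per system (A1, PB, M1_i; V1, AT, M1_L) so that the
#' auditory-articulatory and visual/motor grounding structure is preserved.
#'
#' @param scale `"full"` (12 areas) or `"miniature"` (6 areas).
#' @return A data frame with columns `name`, `system`
#'   (perisylvian/extrasylvian) and `role` (primary/secondary/hub).
#' @export
area_table <- function(scale = c("full", "miniature")) {
  scale <- match.arg(scale)
  full <- data.frame(
    name = c("V1", "TO", "AT", "PF_L", "PM_L", "M1_L",
             "A1", "AB", "PB", "PF_i", "PM_i", "M1_i"),
    system = rep(c("extrasylvian", "perisylvian"), each = 6),
    role = c("primary", "secondary", "hub", "hub", "secondary", "primary",
             "primary", "secondary", "hub", "hub", "secondary", "primary"),
    stringsAsFactors = FALSE
  )
  if (scale == "full") return(full)
  full[full$name %in% c("V1", "AT", "M1_L", "A1", "PB", "M1_i"), , drop = FALSE]
}

#' Between-area edges of the architecture
#'
#' The undirected area-level graph. At full scale it has 22 edges:
#' the two six-area next-neighbour chains, the four hub cross-links between
#' the multimodal areas (AT, PB, PF_i, PF_L), four within-system "jumping"
#' links between non-adjacent areas, and four long-distance links between
#' the temporal and frontal ends of each system. Each undirected edge is
#' realised as two directed sparse projections. The miniature graph keeps
#' the analogous skeleton over its six areas.
#'
#' @param scale `"full"` or `"miniature"`.
#' @return A data frame with columns `from` and `to` (area names).
#' @export
architecture_edges <- function(scale = c("full", "miniature")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    e <- rbind(
      # next-neighbour chains
      c("A1", "AB"), c("AB", "PB"), c("PB", "PF_i"), c("PF_i", "PM_i"),
      c("PM_i", "M1_i"),
      c("V1", "TO"), c("TO", "AT"), c("AT", "PF_L"), c("PF_L", "PM_L"),
      c("PM_L", "M1_L"),
      # hub cross-links
      c("AT", "PB"), c("AT", "PF_i"), c("PB", "PF_L"), c("PF_i", "PF_L"),
      # jumping links
      c("A1", "PB"), c("PF_i", "M1_i"), c("PF_L", "M1_L"), c("V1", "AT"),
      # long-distance links
      c("PB", "PM_i"), c("AB", "PF_i"), c("AT", "PM_L"), c("TO", "PF_L")
    )
  } else {
    e <- rbind(
      c("A1", "PB"), c("PB", "M1_i"),
      c("V1", "AT"), c("AT", "M1_L"),
      c("AT", "PB")
    )
  }
  data.frame(from = e[, 1], to = e[, 2], stringsAsFactors = FALSE)
}

#' Sample a sparse topographic projection between two grids
#'
#' Links a source cell at grid position (r, c) to target cells inside the
#' n x n square centred on the same (homologous) position of the target
#' grid. Each candidate link at offset d is realised independently with
#' probability `p0 * exp(-|d|^2 / (2 sigma^2))`; no link can occur outside
#' the square, and neighbourhoods are clipped (not wrapped) at area
#' borders.
#'
#' @param grid Cells per side of the (square) source and target areas.
#' @param n Neighbourhood side length (odd).
#' @param p0 Peak (zero-offset) connection probability, in (0, 1].
#' @param sigma Gaussian width of the fall-off, in grid units.
#' @param exclude_self Drop the (0, 0) offset (used for within-area
#'   recurrent projections, which have no self-synapses).
#' @return A data frame with columns `pre` and `post`: 1-based cell indices
#'   (column-major over the grid) of the realised links.
#' @export
topographic_sample <- function(grid, n, p0, sigma, exclude_self = FALSE) {
  stopifnot(n %% 2 == 1, p0 > 0, p0 <= 1, sigma > 0)
  h <- (n - 1L) %/% 2L
  rr <- rep(seq_len(grid), times = grid)   # row of each cell, column-major
  cc <- rep(seq_len(grid), each = grid)
  pre_all <- integer(0)
  post_all <- integer(0)
  for (dr in -h:h) {
    for (dc in -h:h) {
      if (exclude_self && dr == 0L && dc == 0L) next
      pr <- p0 * exp(-(dr^2 + dc^2) / (2 * sigma^2))
      tr <- rr + dr
      tc <- cc + dc
      ok <- tr >= 1L & tr <= grid & tc >= 1L & tc <= grid
      idx <- which(ok)
      if (!length(idx)) next
      hit <- idx[stats::runif(length(idx)) < pr]
      if (!length(hit)) next
      pre_all <- c(pre_all, hit)
      post_all <- c(post_all, (tc[hit] - 1L) * grid + tr[hit])
    }
  }
  data.frame(pre = pre_all, post = post_all)
}

#' Fixed local inhibitory loop of one area
#'
#' Each excitatory cell has a twin inhibitory cell at the same grid
#' position. The inhibitory cell sums the spikes of all excitatory cells in
#' its (clipped) n x n neighbourhood with a fixed weight `g_ei`, and
#' inhibits only its twin excitatory cell with fixed weight `-g_ie`. These
#' weights never change during learning.
#'
#' @param grid Cells per side of the area.
#' @param n Inhibitory fan-in neighbourhood side (odd).
#' @param g_ei Excitatory-to-inhibitory weight (each link).
#' @return A data frame with columns `pre` (excitatory cell), `post`
#'   (inhibitory cell) and `w` for the E->I fan-in; the one-to-one I->E twin
#'   link is implied by index identity and carried as a scalar elsewhere.
#' @export
build_inhibitory_loops <- function(grid, n, g_ei) {
  stopifnot(n %% 2 == 1)
  h <- (n - 1L) %/% 2L
  rr <- rep(seq_len(grid), times = grid)
  cc <- rep(seq_len(grid), each = grid)
  pre_all <- integer(0)
  post_all <- integer(0)
  for (dr in -h:h) {
    for (dc in -h:h) {
      sr <- rr + dr
      sc <- cc + dc
      ok <- sr >= 1L & sr <= grid & sc >= 1L & sc <= grid
      idx <- which(ok)
      if (!length(idx)) next
      pre_all <- c(pre_all, (sc[idx] - 1L) * grid + sr[idx])
      post_all <- c(post_all, idx)
    }
  }
  data.frame(pre = pre_all, post = post_all, w = g_ei)
}

#' Build the network connectome
#'
#' Realises the multi-area architecture: per-area recurrent excitatory
#' maps, reciprocal sparse topographic projections for every edge of
#' [architecture_edges()], and the fixed local inhibitory loops. All
#' excitatory-to-excitatory weights (within and between areas) are drawn
#' i.i.d. uniform on `[0, w_init_max]` and are plastic; inhibitory-loop
#' weights are fixed.
#'
#' Uses R's global RNG stream: call `set.seed()` first for a reproducible
#' build.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `spikelex_connectome` with fields
#'   `areas` (area table), `edges` (area edge list), `grid`,
#'   `n_area` (excitatory cells per area), `n_exc` (total excitatory
#'   cells), `area_of` (area index of each excitatory cell),
#'   `W_ee` (sparse `n_exc x n_exc` Matrix, entry (post, pre)),
#'   `W_ei` (sparse E->I fan-in, inhibitory cells indexed like their
#'   excitatory twins), `g_ie` (magnitude of the twin inhibition) and the
#'   structural settings used.
#' @export
build_architecture <- function(config = sim_config()) {
  areas <- area_table(config$scale)
  edges <- architecture_edges(config$scale)
  stopifnot(all(c(edges$from, edges$to) %in% areas$name))
  grid <- config$grid
  A <- grid^2                       # excitatory cells per area
  n_areas <- nrow(areas)
  Ne <- A * n_areas
  off <- function(area_name) (match(area_name, areas$name) - 1L) * A
  sigma_e <- config$sigma_frac * config$n_exc_nb

  pre <- vector("list", n_areas + 2L * nrow(edges))
  post <- pre
  k <- 0L
  for (a in areas$name) {            # within-area recurrent maps
    lk <- topographic_sample(grid, config$n_exc_nb, config$p0, sigma_e,
                             exclude_self = TRUE)
    k <- k + 1L
    pre[[k]] <- lk$pre + off(a)
    post[[k]] <- lk$post + off(a)
  }
  for (i in seq_len(nrow(edges))) {  # reciprocal between-area projections
    for (dir in 1:2) {
      src <- if (dir == 1) edges$from[i] else edges$to[i]
      dst <- if (dir == 1) edges$to[i] else edges$from[i]
      lk <- topographic_sample(grid, config$n_exc_nb, config$p0, sigma_e)
      k <- k + 1L
      pre[[k]] <- lk$pre + off(src)
      post[[k]] <- lk$post + off(dst)
    }
  }
  pre <- unlist(pre)
  post <- unlist(post)
  w <- stats::runif(length(pre), 0, config$w_init_max)
  W_ee <- Matrix::sparseMatrix(i = post, j = pre, x = w, dims = c(Ne, Ne))

  loop <- build_inhibitory_loops(grid, config$n_inh_nb, config$g_ei)
  W_ei <- Matrix::sparseMatrix(
    i = rep(loop$post, n_areas) + rep((seq_len(n_areas) - 1L) * A,
                                      each = nrow(loop)),
    j = rep(loop$pre, n_areas) + rep((seq_len(n_areas) - 1L) * A,
                                     each = nrow(loop)),
    x = rep(loop$w, n_areas), dims = c(Ne, Ne)
  )

  structure(list(
    areas = areas, edges = edges, grid = grid, n_area = A,
    n_exc = Ne, area_of = rep(seq_len(n_areas), each = A),
    W_ee = W_ee, W_ei = W_ei, g_ie = config$g_ie,
    settings = config[c("scale", "n_exc_nb", "n_inh_nb", "p0", "sigma_frac",
                        "w_init_max", "w_max", "g_ei", "g_ie")]
  ), class = "spikelex_connectome")
}

#' @exportS3Method base::print
print.spikelex_connectome <- function(x, ...) {
  cat(sprintf("<spikelex_connectome> %d areas x (%d exc + %d inh) cells = %d cells\n",
              nrow(x$areas), x$n_area, x$n_area, 2L * x$n_exc))
  cat(sprintf("  %d between-area edges, %d E->E synapses, grid %dx%d\n",
              nrow(x$edges), length(x$W_ee@x), x$grid, x$grid))
  invisible(x)
}

#' Index helper: global excitatory-cell ids of one area
#'
#' @param connectome A `spikelex_connectome`.
#' @param area Area name.
#' @return Integer vector of global cell indices.
#' @export
area_cells <- function(connectome, area) {
  a <- match(area, connectome$areas$name)
  if (is.na(a)) stop("unknown area name: ", area)
  (a - 1L) * connectome$n_area + seq_len(connectome$n_area)
}

#' Serialise / restore a connectome
#'
#' Round-trips are lossless (exact array equality). The on-disk form is a
#' single R serialisation containing the sparse triplets and all metadata.
#'
#' @param connectome A `spikelex_connectome`.
#' @param path File path.
#' @return `path` (write) or the restored object (read).
#' @export
write_connectome <- function(connectome, path) {
  saveRDS(connectome, path)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "spikelex_connectome")) stop("not a connectome file: ", path)
  x
}
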