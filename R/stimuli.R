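#' Generate the word stimulus set
#'
#' Each "word" is a triplet of sparse binary activation patterns over the
#' network's primary areas: an auditory pattern in A1 and an articulatory
#' pattern in M1_i for every word, plus a semantic-grounding pattern in V1
#' for object-related words or in M1_L for action-related words. A pattern
#' is a set of `cells_per_pattern` cells drawn uniformly without
#' replacement from the area's grid (19 of 625 cells, about 3%, at full
#' scale); all patterns are drawn independently. Half of the words are
#' object-related, half action-related.
#'
#' Uses R's global RNG; seed beforehand for reproducibility.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `spikelex_stimuli`: a list with `words`
#'   (list of named lists of area-local cell indices), `category`
#'   (`"object"`/`"action"` per word), `pseudowords` (`NULL` until
#'   [make_pseudowords()] is called), `grid` and `cells_per_pattern`.
#' @export
make_word_patterns <- function(config = sim_config()) {
  K <- config$n_words
  A <- config$grid^2
  if (config$cells_per_pattern > A) {
    stop("cells_per_pattern (", config$cells_per_pattern,
         ") exceeds area size (", A, ")")
  }
  category <- c(rep("object", ceiling(K / 2)), rep("action", K %/% 2))
  words <- lapply(seq_len(K), function(w) {
    p <- list(
      A1 = sort(sample.int(A, config$cells_per_pattern)),
      M1_i = sort(sample.int(A, config$cells_per_pattern))
    )
    ground <- if (category[w] == "object") "V1" else "M1_L"
    p[[ground]] <- sort(sample.int(A, config$cells_per_pattern))
    p
  })
  structure(list(words = words, category = category, pseudowords = NULL,
                 grid = config$grid,
                 cells_per_pattern = config$cells_per_pattern,
                 sub_square = config$sub_square),
            class = "spikelex_stimuli")
}

#' Build pseudoword patterns by sub-square recombination
#'
#' The A1 grid is tiled into sub-squares of side `sub_square` (25 tiles of
#' 5x5 cells at full scale; border tiles are clipped when the tile size
#' does not divide the grid). Each pseudoword is assembled tile by tile:
#' the content of tile (r, c) is copied from tile (r, c) of one source
#' word's A1 pattern, so every active cell keeps its spatial position.
#' Sources are balanced: with T tiles and K words each word supplies
#' `floor(T/K)` tiles and the remaining `T mod K` tiles come from words
#' drawn without replacement — at full scale, 2 sub-squares from each of
#' the 12 words plus one extra. When the tile count is not `2K + 1` the
#' same proportional rule applies, with a warning.
#'
#' @param stimuli A `spikelex_stimuli` from [make_word_patterns()].
#' @param n_pseudowords Number of pseudowords (defaults to the word count).
#' @return The `stimuli` object with `pseudowords` filled in: a list of
#'   A1 cell-index vectors, with the per-tile source words attached as
#'   attribute `"sources"` on each pattern.
#' @export
make_pseudowords <- function(stimuli, n_pseudowords = length(stimuli$words)) {
  K <- length(stimuli$words)
  grid <- stimuli$grid
  s <- stimuli$sub_square
  nt <- ceiling(grid / s)
  T_tiles <- nt^2
  if (T_tiles != 2L * K + 1L) {
    warning("tile count (", T_tiles, ") is not 2 * n_words + 1 (",
            2L * K + 1L, "): using proportional sub-square sourcing")
  }
  cell_tile <- function(idx) {          # tile id of each area-local cell
    r <- (idx - 1L) %% grid + 1L
    c <- (idx - 1L) %/% grid + 1L
    (ceiling(c / s) - 1L) * nt + ceiling(r / s)
  }
  all_cells <- seq_len(grid^2)
  tile_of <- cell_tile(all_cells)
  base <- rep(seq_len(K), T_tiles %/% K)
  n_extra <- T_tiles - length(base)
  stimuli$pseudowords <- lapply(seq_len(n_pseudowords), function(pw) {
    extra <- if (n_extra > 0) sample.int(K, n_extra) else integer(0)
    src <- sample(c(base, extra))       # source word of each tile
    cells <- unlist(lapply(seq_len(T_tiles), function(tl) {
      wp <- stimuli$words[[src[tl]]]$A1
      wp[tile_of[wp] == tl]
    }))
    structure(sort(cells), sources = src)
  })
  stimuli
}

#' @exportS3Method base::print
print.spikelex_stimuli <- function(x, ...) {
  cat(sprintf("<spikelex_stimuli> %d words (%d object, %d action), %d-cell patterns\n",
              length(x$words), sum(x$category == "object"),
              sum(x$category == "action"), x$cells_per_pattern))
  if (!is.null(x$pseudowords)) {
    cat(sprintf("  %d pseudowords (sub-square size %d)\n",
                length(x$pseudowords), x$sub_square))
  }
  invisible(x)
}

#' External drive vector for a set of area patterns
#'
#' Builds the per-excitatory-cell stimulus vector: `amp` at each active
#' pattern cell of each nominated area, 0 everywhere else.
#'
#' @param connectome A `spikelex_connectome`.
#' @param pattern Named list of area-local cell-index vectors (names are
#'   area names), e.g. one element of `stimuli$words`, or
#'   `list(A1 = ...)` for auditory-only testing stimulation.
#' @param amp Drive amplitude.
#' @return Numeric vector over all excitatory cells.
#' @export
stimulus_drive <- function(connectome, pattern, amp) {
  ext <- numeric(connectome$n_exc)
  for (a in names(pattern)) {
    ext[area_cells(connectome, a)[pattern[[a]]]] <- amp
  }
  ext
}
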