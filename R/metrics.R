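#' Iowa Gambling index of a session
#'
#' Advantageous-deck picks minus disadvantageous-deck picks:
#' `(#C + #D) - (#A + #B)`. Higher is better reinforcement-guided
#' performance; range is `[-n, n]` with the parity of `n`.
#'
#' @param session Data.frame with a `deck` column of picks in A/B/C/D, or a
#'   character vector of picks.
#' @return Integer IG index.
#' @export
ig_index <- function(session) {
  deck <- if (is.data.frame(session)) session$deck else session
  if (!all(deck %in% c("A", "B", "C", "D")))
    stop("unknown deck symbol: ",
         paste(unique(setdiff(deck, c("A", "B", "C", "D"))), collapse = ", "))
  sum(deck %in% c("C", "D")) - sum(deck %in% c("A", "B"))
}

#' USEQ total score and satisfaction band
#'
#' Sums the six 5-point Likert items of the user-satisfaction questionnaire
#' (total range 6-30) and assigns the published interpretation band:
#' 6-11 low, 12-17 moderate, 18-23 good, 24-30 excellent.
#'
#' @param items Integer vector of exactly 6 item scores in 1-5.
#' @return List with `total` and `band`.
#' @export
useq_total <- function(items) {
  if (length(items) != 6L) stop("USEQ has exactly 6 items")
  if (any(items != round(items)) || any(items < 1 | items > 5))
    stop("items must be integers in 1-5")
  total <- sum(items)
  band <- cut(total, breaks = c(5, 11, 17, 23, 30),
              labels = c("low", "moderate", "good", "excellent"))
  list(total = total, band = as.character(band))
}

#' Stimulating and instrumental risk subscale totals
#'
#' The stimulating-risk subscale has 4 items (total 4-20), the
#' instrumental-risk subscale 3 items (total 3-15), each on a 5-point
#' Likert scale.
#'
#' @param stimulating Integer vector of 4 item scores in 1-5.
#' @param instrumental Integer vector of 3 item scores in 1-5.
#' @return List with `stimulating` and `instrumental` totals.
#' @export
sirq_scores <- function(stimulating, instrumental) {
  if (length(stimulating) != 4L) stop("stimulating-risk subscale has 4 items")
  if (length(instrumental) != 3L) stop("instrumental-risk subscale has 3 items")
  ok <- function(x) all(x == round(x)) && all(x >= 1 & x <= 5)
  if (!ok(stimulating) || !ok(instrumental))
    stop("items must be integers in 1-5")
  list(stimulating = sum(stimulating), instrumental = sum(instrumental))
}

#' Per-block PCA variable selection
#'
#' Runs a principal component analysis on the standardized variables of each
#' theoretical block and retains a variable when its maximal absolute
#' loading, over the components that together explain at least
#' `cum_var` of the block variance, reaches `threshold`. Constant columns
#' are excluded with a warning; near-collinear pairs (|r| > 0.99) flag the
#' later column as redundant.
#'
#' @param raw_table Data.frame of numeric candidate variables.
#' @param block_map Named character vector mapping variable name to block
#'   (default [kdt_block_map()]).
#' @param threshold Minimum absolute loading to retain (default 0.4).
#' @param cum_var Cumulative explained-variance cutoff that fixes the number
#'   of components examined (default 0.7).
#' @return List with `selected` (character vector), `loadings` (per-block
#'   loading matrices), `redundant`, and `dropped` (constant columns).
#' @export
select_variables_pca <- function(raw_table, block_map = kdt_block_map(),
                                 threshold = 0.4, cum_var = 0.7) {
  vars <- intersect(names(block_map), names(raw_table))
  if (length(vars) == 0L) stop("no block_map variables present in table")
  dropped <- vars[vapply(raw_table[vars],
                         function(x) stats::sd(x) == 0, logical(1))]
  if (length(dropped))
    warning("constant columns excluded: ", paste(dropped, collapse = ", "))
  vars <- setdiff(vars, dropped)
  selected <- character(0); redundant <- character(0)
  loadings <- list()
  for (bl in unique(block_map[vars])) {
    bv <- vars[block_map[vars] == bl]
    if (length(bv) < 2L) stop("block '", bl, "' needs >= 2 variables")
    x <- scale(as.matrix(raw_table[bv]))
    if (nrow(x) <= length(bv))
      stop("need more observations than variables per block")
    cm <- stats::cor(x)
    for (i in seq_along(bv)) for (j in seq_len(i - 1L))
      if (abs(cm[i, j]) > 0.99) redundant <- union(redundant, bv[i])
    pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
    pvar <- pc$sdev^2 / sum(pc$sdev^2)
    ncomp <- which(cumsum(pvar) >= cum_var)[1]
    load <- pc$rotation[, seq_len(ncomp), drop = FALSE] %*%
      diag(pc$sdev[seq_len(ncomp)], ncomp)
    loadings[[bl]] <- load
    keep <- bv[apply(abs(load), 1, max) >= threshold]
    selected <- c(selected, keep)
  }
  list(selected = selected, loadings = loadings,
       redundant = redundant, dropped = dropped)
}
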