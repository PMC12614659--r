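## Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Rounds on the decimal scale with ties going away from zero, matching how
#' clinical tables print percentages (base [round()] uses round-half-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Ordered vocabularies for stage components. "x" = not determined; the
## ordering encodes extent of disease so that conflict resolution can take
## the worst documented extent.
.t_levels <- c("x", "0", "is", "1", "2", "3", "4")
.n_levels <- c("x", "0", "1", "2")
.m_levels <- c("x", "0", "1")
.seer_pattern_levels <- c("0", "1", "2", "3", "7", "9")
.seer_levels <- c("0", "1", "2", "3", "4", "5", "7", "9")

stage_rank <- function(value, component) {
  levels <- switch(component,
    T = .t_levels, N = .n_levels, M = .m_levels,
    SEER = c("x", .seer_levels),
    stop("unknown component: ", component)
  )
  match(value, levels)
}

## Highest-extent value among candidates (character), "x" if none.
max_stage <- function(values, component) {
  if (length(values) == 0L) return("x")
  values[which.max(stage_rank(values, component))]
}

is_missing_cell <- function(x) {
  is.na(x) | (is.character(x) & trimws(x) == "")
}
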