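#' @importFrom rlang .data abort warn %||%
#' @importFrom stats qnorm pnorm pt sd rbinom rpois runif quantile setNames
#' @importFrom utils head
NULL

# Enum vocabularies shared across the schemas.
PHASES      <- c("pre", "post")
TRUTH       <- c("cancer", "normal")
LATERALITY  <- c("L", "R", "none")
QUADRANTS   <- c("UO", "UI", "LO", "LI", "central", "none")
VIEWS       <- c("LCC", "RCC", "LMLO", "RMLO")
COMPONENTS  <- c("mass", "microcalcifications", "architectural_distortion",
                 "asymmetry", "focal_asymmetry")
DENSITIES   <- 1:4

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero,
#' the convention used for all displayed percentages (e.g. 139/317 -> 44,
#' 90/139 -> 65). Base [round()] rounds half to even and would disagree on
#' such values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))   # 1  2 -1
#' round_half_away(100 * 139 / 317)     # 44
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a display percentage
#'
#' All internal arithmetic is unrounded; this is the single routine through
#' which any percentage reaches a report.
#'
#' @param p Proportion(s) in `[0, 1]` or percentage points if `scale = 1`.
#' @param digits Decimal places in the display value.
#' @param scale Multiplier applied before rounding (default 100).
#' @return Numeric display value (not a string).
#' @export
display_pct <- function(p, digits = 0, scale = 100) {
  round_half_away(p * scale, digits)
}

# Stable 32-bit sub-seed derived from a master seed and a stream label, so
# that e.g. reader-level sampling can change without perturbing case-level
# sampling. Plain polynomial hash; stays below 2^31.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# Truncated-normal sampler on [lo, hi] by inverse-CDF, so a single uniform
# stream drives it deterministically.
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

stop_cadreader <- function(msg, class) {
  abort(msg, class = c(class, "cadreader_error"))
}

`%g%` <- function(x, default) if (is.null(x) || length(x) == 0) default else x
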