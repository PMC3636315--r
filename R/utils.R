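# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

raise <- function(class, msg, ...) {
  stop(structure(list(message = sprintf(msg, ...), call = NULL),
                 class = c(class, "error", "condition")))
}

config_error <- function(msg, ...) raise("webaudiometry_config_error", msg, ...)
data_error <- function(msg, ...) raise("webaudiometry_data_error", msg, ...)
domain_error <- function(msg, ...) raise("webaudiometry_domain_error", msg, ...)

#' Quantize levels to a step grid (round half up)
#'
#' Audiometric levels are presented on a discrete attenuator grid. The
#' rounding convention is round-half-up: `quantize(42.5, 5)` is 45 and
#' `quantize(-2.5, 5)` is 0. A step of 0 (or less) disables quantization,
#' which the variance-bookkeeping checks rely on.
#'
#' @param x numeric vector of levels in dB.
#' @param step grid step in dB; `step <= 0` returns `x` unchanged.
#' @return numeric vector on the step grid.
#' @export
#' @examples
#' quantize(43, 5)   # 45
#' quantize(42.4, 5) # 40
quantize <- function(x, step = 5) {
  if (!is.numeric(step) || length(step) != 1L || is.na(step))
    domain_error("quantization step must be a single number")
  if (step <= 0) return(x)
  floor(x / step + 0.5) * step
}

# Named substreams derived from one master seed so each stage is
# independently reproducible. Offsets stay < 1024 and the product below
# 2^30, keeping derived seeds valid 32-bit integers.
.substream_offsets <- c(
  cohort = 101L, devices = 211L, series1 = 307L, series2 = 401L,
  series3 = 503L, followup = 601L, procedures = 701L, analysis = 811L
)

substream_seed <- function(master_seed, name) {
  if (!name %in% names(.substream_offsets))
    config_error("unknown random substream '%s'", name)
  base <- as.integer(abs(as.numeric(master_seed)) %% 1048576)
  base * 1024L + .substream_offsets[[name]]
}

with_substream <- function(master_seed, name, expr) {
  set.seed(substream_seed(master_seed, name))
  expr
}

# Round half up at a given number of decimals (base round() is half-even);
# used only for report presentation.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Largest-remainder apportionment of n items over proportions; exact counts.
apportion <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
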