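#' @importFrom methods is new validObject setValidity as slot
#' @importFrom stats quantile setNames median p.adjust phyper pchisq pnorm
#'   pt qnorm rbinom rexp rlnorm rnbinom rnorm runif lm.fit model.matrix
#'   hclust cutree dist t.test rpois
#' @importFrom utils read.delim write.table
NULL

# geometric mean of values floored at `floor` (floor > 0 guards log(0))
geomMean <- function(x, floor = 0.5) {
  exp(mean(log(pmax(x, floor))))
}

# geometric standard deviation: exp of the sample sd of natural logs
geomSD <- function(x, floor = 0.5) {
  lx <- log(pmax(x, floor))
  if (length(lx) < 2L) return(1)
  exp(sd(lx))
}

# log2 with a positivity floor, the transform used throughout the pipeline
log2Floor <- function(x, floor = 0.5) {
  log2(pmax(x, floor))
}

.assertScalarNumber <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# derive a stream-specific 32-bit seed from a master seed
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
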