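#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp pchisq pt pf cor quantile rnorm rbinom runif
#'   p.adjust rgamma complete.cases sd setNames aov anova lm var
#' @importFrom utils head modifyList
NULL

# Run code with a temporary RNG state so seeded operations never disturb the
# caller's stream. Seeds must stay below 2^31 (R integers are 32-bit).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Round half away from zero at a fixed number of digits
#'
#' Reporting helper mirroring the "half-up" convention used when percentages
#' are printed (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

logit <- function(p) log(p / (1 - p))

# Clamp latent logit values so the logistic transform stays strictly inside
# (0,1) in double precision.
clamp_logit <- function(m, lim = 30) {
  if (any(!is.finite(m))) stop("non-finite logit values", call. = FALSE)
  pmin(pmax(m, -lim), lim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
}

# Simple QC accounting container used by the filtering operations.
qc_report <- function(excluded, n_before, n_after) {
  stopifnot(is.data.frame(excluded), all(c("id", "reason") %in% names(excluded)))
  n_excl <- length(unique(excluded$id))
  if (n_before - n_excl != n_after)
    stop(sprintf("QC accounting mismatch: %d before - %d excluded != %d after",
                 n_before, n_excl, n_after), call. = FALSE)
  structure(list(excluded = excluded, n_before = n_before, n_after = n_after),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d -> %d (%d excluded)\n",
              x$n_before, x$n_after, length(unique(x$excluded$id))))
  if (nrow(x$excluded)) print(utils::head(x$excluded, 20))
  invisible(x)
}
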