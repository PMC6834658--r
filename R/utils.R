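#' @useDynLib n2kprior, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rlnorm runif rbinom median cor.test qlnorm plnorm
#' @importFrom utils read.csv write.csv
NULL

# Canonical category sets used throughout.
IUCN_STATUSES <- c("CR", "EN", "VU", "NT", "LC", "NE", "DD")
THREAT_STATUSES <- c("CR", "EN", "VU", "NT")
TAXA <- c("amphibian", "bird", "fish", "mammal", "reptile")

#' Derive a reproducible sub-seed from a master seed and stream indices
#'
#' Mixes a master seed with one or more non-negative stream indices (bootstrap
#' number, run number, stage offset) into an integer seed below 2^31, using a
#' multiplicative congruential hash (multiplier 69069, the classic VAX/Marsaglia
#' constant). Distinct index tuples map to distinct streams with overwhelming
#' probability, and adding later indices never perturbs seeds derived from
#' earlier ones.
#'
#' @param master integer master seed.
#' @param ... non-negative integer stream indices.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
subseed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(master) == 1, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (v in idx) {
    h <- (h * 69069 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(field, "must contain probabilities in [0, 1]")
  }
  invisible(x)
}

check_status <- function(status) {
  bad <- setdiff(unique(status), IUCN_STATUSES)
  if (length(bad) > 0) {
    stop(sprintf("unknown IUCN status: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(status)
}
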