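#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Per-subject (and per-stage) random streams are derived from one master
#' seed by hashing a stable string key, so that adding subjects or permuting
#' file order never reshuffles the streams of existing subjects.
#'
#' @param master integer master seed.
#' @param key character key (e.g. a subject id, optionally suffixed with a
#'   stage name).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' deriveSeed(42, "sub-P001")
deriveSeed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  mod <- 2147483647
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% mod
  x <- (h + (abs(as.numeric(master)) %% mod) * 69621) %% mod
  # avalanche (Lehmer steps): keys or masters that differ only in a final
  # digit must not map to adjacent seeds, or nested derivations produce
  # overlapping seed blocks across runs (shared permutation shuffles)
  for (i in 1:3) x <- (x * 48271) %% mod
  as.integer(x %% (mod - 1) + 1)
}

# integer check helper
.isCount <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

# stratified fold assignment: every fold holds both classes when possible
.stratifiedFolds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# columns of the subject-record table, with requiredness
.recordColumns <- function() {
  list(
    covariates = c("age", "education", "ftnd"),
    clinical = c("bprs_total", "bprs_anxiety_depression",
                 "bprs_lack_of_vitality", "bprs_thinking_disorder",
                 "bprs_activity", "bprs_hostility_suspicion", "hama")
  )
}
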