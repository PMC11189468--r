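`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg, ...) {
  if (cond) rlang::abort(sprintf(msg, ...))
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

check_prob_vector <- function(p, name, len = NULL) {
  abort_if(!is.numeric(p) || any(!is.finite(p)) || any(p < 0),
           "`%s` must be a non-negative numeric vector.", name)
  if (!is.null(len)) abort_if(length(p) != len, "`%s` must have length %d.", name, len)
  abort_if(abs(sum(p) - 1) > 1e-9, "`%s` must sum to 1 (got %.12f).", name, sum(p))
  invisible(p)
}

#' @keywords internal
#' @noRd
fnv1a32 <- function(x) {
  # FNV-1a 32-bit over UTF-8 bytes, split-multiply to stay in double precision
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536; hi <- (h - lo) / 65536
    lo <- bitwXor(lo, b %% 256)
    b_hi <- (b - b %% 256) / 256
    hi <- bitwXor(hi, b_hi)
    h <- hi * 65536 + lo
    h <- (h %% 65536) * 16777619 + (((h - h %% 65536) / 65536 * 16777619) %% 65536) * 65536
    h <- h %% 4294967296
  }
  h
}

# deterministic uniform in [0, 1) keyed by strings (patient ids etc.)
hash_unit <- function(keys) {
  vapply(keys, fnv1a32, numeric(1), USE.NAMES = FALSE) / 4294967296
}

geometric_mean <- function(x) exp(mean(log(x)))

# sub-seed derivation: keep below 2^31
derive_seed <- function(seed, label) {
  as.integer((seed + fnv1a32(label)) %% 2147483647)
}
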