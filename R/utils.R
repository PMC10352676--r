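# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#: molar gas constant, kJ mol^-1 K^-1
R_GAS <- 0.008314

#: reference leaf temperature, K (25 degrees C)
T_REF <- 298.15

# Evaluate `code` without disturbing the caller's RNG stream. Used wherever a
# function seeds its own reproducible stream (generator, random forest).
with_preserved_seed <- function(code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  force(code)
}

# Stable 31-adic string hash folded into [0, 2^31 - 2]; derives independent,
# reproducible per-record streams from one master seed. Doubles stay exact
# because intermediates never exceed 2^53.
hash_seed <- function(seed, ...) {
  modulus <- 2147483647
  key <- paste(c(format(seed), ...), collapse = "|")
  h <- abs(as.double(seed)) %% modulus
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% modulus
  as.integer(h)
}

stop_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

check_tk <- function(tk) {
  if (!is.numeric(tk) || any(!is.finite(tk)) || any(tk < 273) || any(tk > 323)) {
    stop("leaf temperature must lie within [273, 323] K", call. = FALSE)
  }
  invisible(tk)
}

signif_df <- function(df, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}
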