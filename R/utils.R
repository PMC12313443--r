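# Internal helpers shared across modules.

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1),
# used to derive independent per-unit RNG seeds from a master seed so that
# results do not depend on unit processing order.
stable_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Shannon entropy of a non-negative weight vector, natural log, 0 ln 0 := 0.
entropy_nats <- function(w) {
  w <- w[w > 0]
  if (!length(w)) return(0)
  p <- w / sum(w)
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_unit_cols <- function(df, what = "table") {
  miss <- setdiff(unit_key_cols, names(df))
  if (length(miss))
    stop(what, " is missing unit-key column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
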