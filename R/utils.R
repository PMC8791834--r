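# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible substream seed from a master seed and a fixed offset.
# Offsets are small constants documented at each call site; results stay
# below 2^31 - 1 so they are valid R integer seeds.
substream_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000 + offset) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

geomean <- function(x, offset = 0) {
  stopifnot(all(x + offset > 0))
  exp(mean(log(x + offset)))
}

# Wilson score interval for a binomial proportion (the default interval of
# the binconf-style tools this field uses).
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# Largest-remainder rounding of `counts` rescaled to sum to `total`.
largest_remainder_round <- function(counts, total) {
  stopifnot(total >= 0, all(counts >= 0))
  if (sum(counts) == 0) return(rep(0L, length(counts)))
  raw <- counts / sum(counts) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

rcb_levels <- function() c("RCB-III", "RCB-II", "RCB-I", "pCR")

as_rcb_factor <- function(x) {
  f <- factor(as.character(x), levels = rcb_levels(), ordered = TRUE)
  if (anyNA(f) && !anyNA(x)) {
    stop("RCB labels must be one of: ", paste(rcb_levels(), collapse = ", "))
  }
  f
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
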