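#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.125 -> 0.13 at two
#' decimals), the convention used throughout the reporting tables. Base R's
#' [round()] uses banker's rounding, which is unsuitable for reproducing
#' printed half-up values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.675, 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Canonical unordered-dyad key "A|B" with A < B lexicographically.
dyad_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

# Split "A|B" back into a 2-column character matrix.
split_dyad <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  t(vapply(parts, function(p) p[1:2], character(2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Construct a per-dyad distance series
#'
#' Lightweight container for one unordered dyad's cleaned 1 Hz distance
#' stream. Timestamps are epoch seconds, strictly increasing; gaps (removed
#' samples) are simply absent timestamps.
#'
#' @param a,b animal identifiers (order is irrelevant; stored sorted).
#' @param t numeric vector of epoch seconds, strictly increasing.
#' @param d numeric vector of distances in cm, same length as `t`.
#' @param provenance named integer vector of per-filter removal counts.
#' @return an object of class `distance_series`.
#' @export
distance_series <- function(a, b, t, d, provenance = integer(0)) {
  stop_if(length(t) != length(d), "t and d must have equal length")
  o <- order(t)
  t <- t[o]; d <- d[o]
  stop_if(anyDuplicated(t) > 0, "duplicate timestamps in distance_series")
  ids <- sort(c(a, b))
  structure(
    list(dyad = ids, t = as.numeric(t), d = as.numeric(d),
         provenance = provenance),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series %s|%s: %d samples", x$dyad[1], x$dyad[2],
              length(x$t)))
  if (length(x$t)) {
    cat(sprintf(", t %.0f..%.0f s, median %.0f cm",
                min(x$t), max(x$t), stats::median(x$d)))
  }
  cat(">\n")
  invisible(x)
}
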