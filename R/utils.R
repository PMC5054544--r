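`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_cid <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_cid <- function(...) warning(sprintf(...), call. = FALSE)

# Read all lines from a path or connection, UTF-8.
#' @noRd
read_lines_utf8 <- function(stream) {
  if (inherits(stream, "connection")) {
    readLines(stream, warn = FALSE, encoding = "UTF-8")
  } else {
    readLines(stream, warn = FALSE, encoding = "UTF-8")
  }
}

#' @noRd
write_lines_utf8 <- function(lines, stream) {
  if (inherits(stream, "connection")) {
    writeLines(lines, stream, useBytes = FALSE)
  } else {
    con <- file(stream, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
  }
}

# Run code with a temporarily fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Empty feature vector: named numeric of length 0.
#' @noRd
empty_fv <- function() {
  x <- numeric(0)
  names(x) <- character(0)
  x
}

# Add sparse named numeric vectors (union of names, missing = 0).
#' @noRd
fv_add <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  nm <- union(names(a), names(b))
  out <- numeric(length(nm))
  names(out) <- nm
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

# Increment counts for a character vector of feature names.
#' @noRd
fv_count <- function(names_vec, prefix = "") {
  if (length(names_vec) == 0L) return(empty_fv())
  tab <- table(paste0(prefix, names_vec))
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}
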