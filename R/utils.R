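#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange select bind_rows left_join pull distinct
#' @importFrom purrr map map_chr map_dbl map_int map_lgl pmap keep
#' @importFrom stringr str_detect str_trim str_split str_replace_all
NULL

# Error taxonomy. Every user-facing failure is classed so the CLI can map it
# to a stable exit status (usage 1, permission 2, data/format 3, not found 4).
stop_usage <- function(msg) abort(msg, class = c("prodis_usage_error", "prodis_error"))
stop_permission <- function(msg) abort(msg, class = c("prodis_permission_error", "prodis_error"))
stop_format <- function(msg) abort(msg, class = c("prodis_format_error", "prodis_error"))
stop_not_found <- function(msg) abort(msg, class = c("prodis_not_found_error", "prodis_error"))
stop_integrity <- function(msg) abort(msg, class = c("prodis_integrity_error", "prodis_format_error", "prodis_error"))
stop_auth <- function(msg) abort(msg, class = c("prodis_auth_error", "prodis_permission_error", "prodis_error"))

#' SHA-256 digest of a file or character scalar
#'
#' Content addressing for the managed file store and for submission
#' manifests. Files are hashed over their raw bytes.
#'
#' @param path Path to an existing file.
#' @return Lower-case hex digest (64 characters).
#' @export
sha256_file <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("file not found: %s", path))
  digest::digest(path, algo = "sha256", file = TRUE)
}

sha256_string <- function(x) {
  digest::digest(x, algo = "sha256", serialize = FALSE)
}

# Salted, deliberately iterated password hash. The iteration count slows
# brute-force attempts; the salt defeats rainbow tables.
hash_password <- function(password, salt, iterations = 5000L) {
  h <- paste0(salt, ":", password)
  for (i in seq_len(iterations)) h <- sha256_string(h)
  h
}

random_salt <- function() {
  paste(sprintf("%02x", sample(0:255, 16, replace = TRUE)), collapse = "")
}

check_iso_date <- function(date) {
  if (is.null(date) || is.na(date) || !is.character(date)) {
    stop_usage("date must be an ISO-8601 'YYYY-MM-DD' string")
  }
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", date) || is.na(as.Date(date, format = "%Y-%m-%d"))) {
    stop_usage(sprintf("invalid ISO-8601 date: %s", date))
  }
  invisible(date)
}

check_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop_usage(sprintf("%s must be a nonempty string", what))
  }
  invisible(x)
}

check_id <- function(x, what = "id") {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x) || x < 1) {
    stop_usage(sprintf("%s must be a single positive integer", what))
  }
  as.integer(x)
}

# Named pseudorandom streams: each generator derives its own seed from the
# user seed plus a stream label, so adding a generator never perturbs the
# output of the others. The derived seed stays below 2^31 - 1.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  force(code)
}

# Numeric formatting used by the text writers; fixed decimal places, no
# scientific notation, so output is byte-stable across platforms.
fmt_num <- function(x, digits) {
  formatC(x, format = "f", digits = digits)
}
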