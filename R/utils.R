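#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

.log_levels <- c(DEBUG = 10L, INFO = 20L, WARNING = 30L, ERROR = 40L)

#' Set the logging threshold
#'
#' Messages below the threshold are suppressed. The default threshold is
#' `"WARNING"` so that library use is quiet; the command-line interface raises
#' it to `"INFO"`.
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARNING"`, `"ERROR"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("WARNING", "DEBUG", "INFO", "ERROR")) {
  level <- match.arg(level)
  old <- getOption("covomics.log_level", "WARNING")
  options(covomics.log_level = level)
  invisible(old)
}

cov_log <- function(level, fmt, ...) {
  threshold <- getOption("covomics.log_level", "WARNING")
  if (.log_levels[[level]] < .log_levels[[threshold]]) return(invisible(NULL))
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  message(sprintf("[%s] %s", level, msg))
  invisible(NULL)
}

#' Derive a stream-specific seed from a master seed
#'
#' Every stochastic procedure in the package draws from its own stream, keyed
#' by a short string, so that adding a new random step never perturbs the
#' draws of existing ones. The derivation is a fixed integer hash of the key
#' folded into the master seed modulo 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param key Stream name (character scalar).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes) * 131) %% 1000003
  as.integer((abs(seed) %% 65521 * 7919 + h * 31 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the length-1 surprise
sample_ids <- function(pool, size) pool[sample.int(length(pool), size)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
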