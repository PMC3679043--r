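# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded generators behave as pure functions.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a stage-specific seed from a master seed
#'
#' Stable fan-out of one master seed into per-stage seeds: hashing the stage
#' name means adding a new pipeline stage never perturbs the random streams
#' of existing stages. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master single integer master seed.
#' @param stage character stage label.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, Park-Miller modulus
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  s <- ((abs(master) %% m) * 48271 + h) %% m
  as.integer(max(1, s))
}

stop_if_not_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", what), call. = FALSE)
  }
  invisible(x)
}

# base-pair formatting for print methods
fmt_bp <- function(n) formatC(n, format = "d", big.mark = ",")

# plain-data.frame views of the package's data.frame subclasses (drop the
# class tag and any summary attributes so comparisons see only the data)
#' @export
as.data.frame.region_set <- function(x, ...) strip_df(x)
#' @export
as.data.frame.read_set <- function(x, ...) strip_df(x)
#' @export
as.data.frame.truth_genotypes <- function(x, ...) strip_df(x)
#' @export
as.data.frame.call_set <- function(x, ...) strip_df(x)
#' @export
as.data.frame.window_table <- function(x, ...) strip_df(x)
#' @export
as.data.frame.coverage_histogram <- function(x, ...) strip_df(x)

strip_df <- function(x) {
  out <- x
  attributes(out) <- list(names = names(x), row.names = attr(x, "row.names"),
                          class = "data.frame")
  out
}
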