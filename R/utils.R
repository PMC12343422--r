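#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from a global seed. Counter-based so stages
# can be rerun independently yet reproducibly; kept below 2^31.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(simulate = 11L, train = 23L, segment = 37L, metrics = 53L,
               stats = 71L, report = 89L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(as.character(stage))) %% 997L
  as.integer((as.numeric(seed) * 1103L + off * 12289L) %% 2147483587)
}

stop_hepavol <- function(class, msg, ...) {
  stop(structure(class = c(class, "hepavol_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
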