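#' @keywords internal
"_PACKAGE"

## Condition system ----------------------------------------------------------
##
## Every error raised by the package carries a subclass of "vs_error" naming
## the failing stage, so callers (and the CLI exit-code map) can dispatch on
## the error class rather than on message text.

vs_error_classes <- c(
  input = "vs_input_error", structure = "vs_structure_error",
  pocket = "vs_pocket_error", generation = "vs_generation_error",
  docking = "vs_docking_error", search = "vs_search_error",
  rank = "vs_rank_error", parameter = "vs_parameter_error",
  encoding = "vs_encoding_error", evaluation = "vs_evaluation_error",
  environment = "vs_environment_error", io = "vs_io_error"
)

vs_stop <- function(kind, msg, ..., data = NULL) {
  kind <- match.arg(kind, names(vs_error_classes))
  cond <- structure(
    class = c(vs_error_classes[[kind]], "vs_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), data = data)
  )
  stop(cond)
}

#' Map a condition to the pipeline's exit-code convention
#'
#' Input errors map to 2, pocket errors to 3, generation errors to 4, docking
#' errors to 5, search/ranking errors to 6, anything else to 1.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @export
vs_exit_code <- function(cond) {
  cls <- class(cond)
  if (any(cls %in% c("vs_input_error", "vs_io_error", "vs_parameter_error",
                     "vs_structure_error"))) return(2L)
  if ("vs_pocket_error" %in% cls) return(3L)
  if ("vs_generation_error" %in% cls) return(4L)
  if (any(cls %in% c("vs_docking_error", "vs_environment_error"))) return(5L)
  if (any(cls %in% c("vs_search_error", "vs_rank_error", "vs_encoding_error",
                     "vs_evaluation_error"))) return(6L)
  1L
}

## Logging -------------------------------------------------------------------

vs_log <- function(stage, msg, ...) {
  if (isTRUE(getOption("vscreenr.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
  invisible(NULL)
}

## Deterministic hashing -----------------------------------------------------
##
## A small polynomial hash over a 31-bit field. It is used wherever the
## package needs process-independent determinism (mock docking energies,
## fingerprint identifiers, config hashes); R's own RNG state is never
## involved, so the same inputs give the same value in any session.

VS_HASH_MOD <- 2147483647  # 2^31 - 1, keeps double arithmetic exact

vs_hash_string <- function(s) {
  b <- utf8ToInt(s)
  h <- 7
  for (x in b) h <- (h * 31 + x) %% VS_HASH_MOD
  h
}

## Fold a numeric vector into the running hash; vectorised over atoms when
## `h` is a vector and `x` a matrix column.
vs_hash_mix <- function(h, x) (h * 31 + (x %% VS_HASH_MOD)) %% VS_HASH_MOD

## Uniform [0, 1) deviate derived from a string, independent of the RNG.
vs_hash_unit <- function(s) vs_hash_string(s) / VS_HASH_MOD

## Scoped RNG ----------------------------------------------------------------
##
## Evaluate `expr` under a fixed seed without disturbing the caller's RNG
## stream. All seeded behaviour in the package goes through this helper.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    vs_stop("parameter", "seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Derive a child seed from a base seed and a label, staying below 2^31.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + vs_hash_string(as.character(label))) %%
               .Machine$integer.max)
}

## Misc ----------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x)
}
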