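# Internal helpers: seeded evaluation that restores the caller's RNG state,
# and a deterministic master-seed -> child-seed splitting rule so results do
# not depend on execution order across trials.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Fixed affine splitting rule modulo a Mersenne prime; children for distinct
#' indices are distinct and independent of the order in which work units are
#' processed. Always below 2^31.
#'
#' @param master integer master seed.
#' @param index non-negative integer work-unit index.
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 * 48271 +
                as.numeric(index) * 8191) %% 2147483629)
}

stop_ierp <- function(msg, class) {
  stop(structure(class = c(class, "ierp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# numeric formatting that round-trips doubles exactly
fmt_full <- function(x) formatC(x, format = "g", digits = 17)
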