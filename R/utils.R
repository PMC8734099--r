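# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# One master seed drives every stochastic stage through independent derived
# streams; the salt names the stage so streams never collide.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  codes <- utf8ToInt(salt)
  h <- sum(as.double(codes) * seq_along(codes))
  as.integer((abs(as.double(seed)) * 7919 + h * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an R object via its serialization, used for no-retraining checks
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version 3 serialization without header variability
  con <- file(f, "wb")
  serialize(x, con, version = 3L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

stop2 <- function(...) stop(..., call. = FALSE)
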