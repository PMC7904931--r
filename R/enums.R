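# Controlled vocabularies of the study design.  Tokens are canonical
# upper-case; readers accept any case.

#' Controlled vocabulary: lipid systems
#'
#' The three LUV compositions of the study design: pure POPC (liquid
#' disordered), POPC:cholesterol 1:1 (liquid ordered) and the raft-mimicking
#' ternary POPC:cholesterol:PSM 1:1:1 (ld/lo coexistence).  All proportions
#' are molar.
#'
#' @return Character vector of canonical tokens.
#' @export
lipid_systems <- function() c("POPC", "POPC_CHOL", "POPC_CHOL_PSM")

#' Controlled vocabulary: compounds
#'
#' Compound tokens in the canonical report order: the vehicle control, the
#' three polyphenol aglycones with their C-glucosides, and the O-glucoside
#' phlorizin.  `G8` is 8-glucosylgenistein, `GLCRESVERATROL` is
#' 4-glucosylresveratrol.
#'
#' @return Character vector of canonical tokens.
#' @export
compounds <- function() {
  c("CONTROL", "PHLORETIN", "NOTHOFAGIN", "PHLORIZIN", "GENISTEIN",
    "G8", "RESVERATROL", "GLCRESVERATROL")
}

#' Controlled vocabulary: probes
#'
#' @return Character vector of canonical probe tokens: the
#'   voltage-sensitive styryl dye di-8-ANEPPS and the acyl-chain order probe
#'   DPH-PC.
#' @export
probes <- function() c("DI8ANEPPS", "DPHPC")

# map a token onto a controlled vocabulary, case-insensitively
match_enum <- function(x, vocab, field) {
  x <- toupper(trimws(as.character(x)))
  bad <- !(x %in% vocab)
  if (any(bad)) {
    stop(sprintf("field '%s': unknown token '%s' (expected one of: %s)",
                 field, x[bad][1], paste(vocab, collapse = ", ")),
         call. = FALSE)
  }
  x
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Run expr with a local RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards.  All package randomness flows through
# this helper so generation never leaks hidden global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("field 'seed': must be a single integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derivation (kept below 2^31).
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 8191) %% 2147483587)
}
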