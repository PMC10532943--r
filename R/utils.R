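# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never clobber user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index)) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stopf("'%s' must be a probability in [0, 1]", name)
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    stopf("'%s' must be a single positive number", name)
  }
  as.numeric(x)
}

# rpart needs syntactic column names; map gene ids to safe aliases and back.
safe_gene_frame <- function(x, genes) {
  safe <- paste0("V", seq_along(genes))
  df <- as.data.frame(x[, genes, drop = FALSE])
  colnames(df) <- safe
  list(frame = df, safe = safe, genes = genes)
}
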