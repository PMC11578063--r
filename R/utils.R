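# Internal helpers: seeded RNG streams and small validators.

# Deterministic 31-bit stream seed from a base seed and a string key, so each
# genome / branch / fixture draws from its own stream regardless of the order
# in which simulation steps run.
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state.  `seed` is forced first so a
# caller's RNG draw in the argument is not rewound by the state restore.
with_seed <- function(seed, expr) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

as_character_seq <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet")) {
    as.character(x)
  } else {
    as.character(x)
  }
}

#' @importFrom methods is
NULL

# Excel-style letter labels: A..Z, AA, AB, ...
letter_labels <- function(n) {
  if (n <= 0) return(character(0))
  lab <- character(n)
  for (i in seq_len(n)) {
    k <- i
    s <- ""
    while (k > 0) {
      r <- (k - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      k <- (k - 1) %/% 26
    }
    lab[i] <- s
  }
  lab
}
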