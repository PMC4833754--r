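# shared fixtures: built once per test run, in code

toy_dimer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_dimer(seed = 1)
    cache
  }
})

toy_bodies <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- toy_dimer()
      cache <<- define_rigid_bodies(st, attr(st, "segments"))
    }
    cache
  }
})

# small random structure of mixed elements for Debye oracles
random_structure <- function(n = 50, seed = 7, elements = c("C", "N", "O")) {
  set.seed(seed)
  structure_from_atoms(data.frame(
    element = sample(elements, n, replace = TRUE),
    resno = seq_len(n), chain = "A",
    x = runif(n, 0, 20), y = runif(n, 0, 20), z = runif(n, 0, 20),
    stringsAsFactors = FALSE))
}

# brute-force O(N^2) Debye oracle in plain R, independent of the C++ path
debye_oracle <- function(structure, q, mode = "vacuum") {
  n <- nrow(structure)
  fq <- t(vapply(seq_len(n), function(i) {
    effective_form_factor(structure$element[i], q, mode,
                          h_count = structure$h_count[i])
  }, numeric(length(q))))
  xyz <- coords(structure)
  I <- numeric(length(q))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s <- ifelse(q * r < 1e-12, 1, sin(q * r) / (q * r))
      I <- I + fq[i, ] * fq[j, ] * s
    }
  }
  I
}
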