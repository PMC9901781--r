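# Shared fixtures: everything is built in code at test time.

freq11 <- audiogram_frequencies()

# small dense matrix on an arbitrary frequency subset, values away from the
# clip bounds so interpolation/regression oracles are exact
tiny_dense <- function(n = 6, freqs = c(125, 250, 500, 1000), seed = 1) {
  set.seed(seed)
  audiogram_matrix(matrix(runif(n * length(freqs), 20, 100), n),
                   frequencies = freqs)
}

# write an audiogram CSV fixture from a data.frame-like list of columns
write_fixture_csv <- function(cols, path = tempfile(fileext = ".csv")) {
  df <- as.data.frame(cols, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  path
}

# dense synthetic set under the generator's default (study) conditions
gen_dense <- function(n, seed = 1, ...) {
  generate_dense(generator_params(n = n, seed = seed, ...))
}

gen_sparse <- function(n, seed = 1, ...) {
  generate_sparse(generator_params(n = n, seed = seed, ...))
}

# numeric matrix contents without class or dimnames (element extraction from
# a column-named matrix otherwise yields named scalars)
vals <- function(m) {
  v <- unclass(m)
  dimnames(v) <- NULL
  attributes(v)[setdiff(names(attributes(v)), "dim")] <- NULL
  v
}

# pull imputed values for truth records
scores_for <- function(completed, truth) {
  audimpute:::score_against_truth(completed, truth)
}
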