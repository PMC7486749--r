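# Shared fixtures, built in code.

# small two-class matrix with `strong` informative columns (mean shift
# `effect` in class B) and noise columns
make_two_class_matrix <- function(n_per_class = 4, p = 10, strong = 1,
                                  effect = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("lip", 1:p)))
  labels <- rep(c("A", "B"), each = n_per_class)
  for (j in seq_len(strong)) X[labels == "B", j] <- X[labels == "B", j] + effect
  list(X = X, labels = labels)
}

# tiny long-format lipidomics TSV on disk; returns the path
write_long_fixture <- function(dir = tempdir()) {
  path <- file.path(dir, "toy_long.tsv")
  df <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2", "s2"),
    lipid = c("Cer - 34:1:2", "PC - 16:0:0;18:1:0", "Chol",
              "Cer - 34:1:2", "PC - 16:0:0;18:1:0", "Chol"),
    pmol = c(2, 3, 5, 1, 1, 2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal one-plate screen table: readouts given per (role, replicate)
make_mini_screen <- function(readouts, n_rep = 1, condition = "growth") {
  do.call(rbind, lapply(seq_len(n_rep), function(r) {
    data.frame(plate = sprintf("P1_%s_r%d", condition, r),
               well = sprintf("A%02d", seq_along(readouts$value)),
               target = readouts$target, role = readouts$role,
               condition = condition, replicate = r,
               readout = readouts$value, stringsAsFactors = FALSE)
  }))
}

candidate_list_path <- function() system.file("extdata", "candidate_species.txt", package = "lipidisc")
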