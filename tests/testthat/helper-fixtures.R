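# In-code fixtures: everything is generated at test time.

# Small, fast synthetic cohort for unit tests (not the acceptance-scale
# default fixture).
tiny_cohort <- function(n_patients_per_class = 4, cells_per_sample = 300,
                        effect = 1.5, seed = 7) {
  generate_cohort(default_fixture_specs(effect = effect),
                  n_patients_per_class = n_patients_per_class,
                  cells_per_sample = cells_per_sample, seed = seed)
}

tiny_ensemble <- function(synth, k_per_sample = 20, k_prime = 5,
                          n_iterations = 3, seed = 11) {
  repeated_metacluster(synth$cohort, k_per_sample = k_per_sample,
                       k_prime = k_prime, n_iterations = n_iterations,
                       master_seed = seed)
}

# Minimal FCS3.0 writer (float32 little-endian, LIST mode) so the FCS
# reading path can be round-trip tested against files built in code.
write_test_fcs <- function(path, values, channel_names = colnames(values)) {
  values <- as.matrix(values)
  n_par <- ncol(values)
  n_tot <- nrow(values)
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    kv <- c(kv, sprintf("$P%dN", i), channel_names[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
  }
  text_seg <- paste0("/", paste(kv, collapse = "/"), "/")
  text_begin <- 58
  text_end <- text_begin + nchar(text_seg) - 1
  data_begin <- text_end + 1
  data_end <- data_begin + 4 * n_par * n_tot - 1
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0, 0)
  stopifnot(nchar(header) == 58)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_seg, con, eos = NULL)
  writeBin(as.vector(t(values)), con, size = 4, endian = "little")
  invisible(path)
}

# write a tiny csv cohort on disk and return its manifest path
write_tiny_disk_cohort <- function(dir, ...) {
  synth <- tiny_cohort(...)
  write_cohort_csv(synth, dir)
}
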