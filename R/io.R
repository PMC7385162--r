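#' Single-sample cell matrix
#'
#' Container for one sample's transformed expression values: cells in
#' rows, analysis channels (phenotypic + functional, panel order) in
#' columns. Input files are assumed pre-gated (singlet live leukocytes);
#' no gating happens here.
#'
#' @param sample_id sample identifier.
#' @param values numeric cells x channels matrix, no missing values.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(sample_id, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1) stop("cell matrix must contain at least one cell")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("cell matrix for sample '", sample_id, "' contains missing/non-finite values")
  }
  structure(list(sample_id = as.character(sample_id), values = values,
                 n_cells = nrow(values)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix '%s': %d cells x %d channels\n",
              x$sample_id, x$n_cells, ncol(x$values)))
  invisible(x)
}

# ---- FCS 3.0 / 3.1 reading --------------------------------------------------
# No FCS reader ships with this package's dependency stack, so a compact
# reader for the common CyTOF case is implemented here: LIST-mode data,
# datatype F (float32), D (float64) or I (uniform 16/32-bit unsigned),
# with $PnE log amplification and $PnG gain linearization.

fcs_read_header_offsets <- function(con) {
  seek(con, 0)
  version <- rawToChar(readBin(con, "raw", 6))
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' (FCS3.0/3.1 supported)")
  }
  readBin(con, "raw", 4) # spaces
  offs <- vapply(1:6, function(i) {
    as.numeric(trimws(rawToChar(readBin(con, "raw", 8))))
  }, numeric(1))
  list(version = version, text = offs[1:2], data = offs[3:4])
}

fcs_parse_text <- function(con, begin, end) {
  seek(con, begin)
  raw_txt <- readBin(con, "raw", end - begin + 1)
  txt <- rawToChar(raw_txt)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- parts[seq(1, length(parts), by = 2)]
  val <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(val), toupper(trimws(kw)))
}

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- fcs_read_header_offsets(con)
  kw <- fcs_parse_text(con, hdr$text[1], hdr$text[2])
  need <- function(k) {
    if (is.null(kw[[k]])) stop("FCS file missing required keyword ", k, ": ", path)
    kw[[k]]
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  mode <- toupper(need("$MODE"))
  if (mode != "L") stop("only LIST-mode ($MODE L) FCS data is supported")
  byteord <- gsub("\\s", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  data_beg <- hdr$data[1]
  data_end <- hdr$data[2]
  if (data_beg == 0 || data_end == 0) {
    data_beg <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  ch_names <- vapply(seq_len(n_par), function(i) {
    nm <- kw[[sprintf("$P%dN", i)]]
    if (is.null(nm)) sprintf("P%d", i) else nm
  }, character(1))
  bits <- vapply(seq_len(n_par), function(i) as.integer(need(sprintf("$P%dB", i))),
                 integer(1))
  seek(con, data_beg)
  n_values <- n_par * n_tot
  if (dtype == "F") {
    x <- readBin(con, "double", n = n_values, size = 4, endian = endian)
  } else if (dtype == "D") {
    x <- readBin(con, "double", n = n_values, size = 8, endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1 || !unique(bits) %in% c(16, 32)) {
      stop("integer FCS data supported only with uniform 16- or 32-bit channels")
    }
    b <- unique(bits)
    if (b == 16) {
      x <- readBin(con, "integer", n = n_values, size = 2, signed = FALSE,
                   endian = endian)
      x <- as.double(x)
    } else {
      x <- readBin(con, "integer", n = n_values, size = 4, endian = endian)
      x <- as.double(x)
      x[x < 0] <- x[x < 0] + 2^32
    }
  } else {
    stop("unsupported $DATATYPE '", dtype, "'")
  }
  if (length(x) != n_values) stop("truncated FCS data segment: ", path)
  m <- matrix(x, nrow = n_tot, ncol = n_par, byrow = TRUE)
  # standard linearization: log amplification ($PnE) else gain ($PnG)
  for (i in seq_len(n_par)) {
    pe <- kw[[sprintf("$P%dE", i)]]
    if (!is.null(pe)) {
      fs <- as.numeric(strsplit(pe, ",")[[1]])
      if (length(fs) == 2 && fs[1] > 0) {
        rng <- as.numeric(kw[[sprintf("$P%dR", i)]])
        f2 <- if (fs[2] == 0) 1 else fs[2]
        m[, i] <- f2 * 10^(fs[1] * m[, i] / rng)
        next
      }
    }
    pg <- kw[[sprintf("$P%dG", i)]]
    if (!is.null(pg)) {
      g <- as.numeric(pg)
      if (is.finite(g) && g > 0 && g != 1) m[, i] <- m[, i] / g
    }
  }
  colnames(m) <- ch_names
  m
}

is_fcs_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(rawToChar(readBin(con, "raw", 3)), error = function(e) "")
  identical(magic, "FCS")
}

# ---- sample / cohort loading ------------------------------------------------

#' Read one cytometry sample
#'
#' Reads an FCS 3.0/3.1 file or a headered CSV (comma-separated, header
#' row of channel names, one cell per row), checks that every panel
#' channel is present, drops excluded channels, reorders columns to
#' panel order and applies the per-channel transform.
#'
#' @param path path to the sample file.
#' @param panel a [marker_panel()].
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return A [cell_matrix()] of transformed expression over the
#'   non-excluded panel channels.
#' @export
read_sample <- function(path, panel, sample_id = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  if (!file.exists(path)) stop("cannot read sample file (not found): ", path)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  raw <- if (is_fcs_file(path)) {
    read_fcs(path)
  } else {
    as.matrix(data.table::fread(path, header = TRUE))
  }
  missing_ch <- setdiff(panel$name, colnames(raw))
  # channels marked excluded may legitimately be absent from exports
  missing_ch <- setdiff(missing_ch,
                        panel$name[panel$role == "excluded"])
  if (length(missing_ch)) {
    stop("channel mismatch in '", path, "': missing channel(s) ",
         paste(missing_ch, collapse = ", "))
  }
  keep <- panel_channels(panel)
  values <- raw[, keep, drop = FALSE]
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    stop("sample '", sample_id, "' contains missing values after loading")
  }
  cell_matrix(sample_id, apply_panel_transform(values, panel))
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with required columns `sample_id`, `patient_id`,
#' `class` (0/1) and `path`.
#'
#' @param path manifest CSV path.
#' @return data.frame with the four manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  man <- as.data.frame(data.table::fread(path, header = TRUE,
                                         colClasses = list(character = "sample_id")))
  required <- c("sample_id", "patient_id", "class", "path")
  miss <- setdiff(required, names(man))
  if (length(miss)) stop("manifest missing required column(s): ",
                         paste(miss, collapse = ", "))
  man$sample_id <- as.character(man$sample_id)
  man$patient_id <- as.character(man$patient_id)
  man$path <- as.character(man$path)
  man[, required]
}

#' Validate cohort metadata
#'
#' Aggregates all metadata problems (duplicate sample ids, labels
#' outside \{0,1\}, patients with samples in both classes, missing
#' files) into a single error report.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param check_paths if `TRUE`, verify that every `path` exists.
#' @return invisibly `TRUE`; stops with the aggregated report otherwise.
#' @export
validate_manifest <- function(manifest, check_paths = TRUE) {
  problems <- character(0)
  if (nrow(manifest) == 0) stop("no samples in manifest")
  dup <- unique(manifest$sample_id[duplicated(manifest$sample_id)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate sample_id: ",
                                   paste(dup, collapse = ", ")))
  }
  bad_class <- !manifest$class %in% c(0, 1)
  if (any(bad_class)) {
    problems <- c(problems,
                  paste0("class label outside {0,1} for sample(s): ",
                         paste(manifest$sample_id[bad_class], collapse = ", ")))
  }
  split_classes <- tapply(manifest$class, manifest$patient_id,
                          function(x) length(unique(x)))
  mixed <- names(split_classes)[split_classes > 1]
  if (length(mixed)) {
    problems <- c(problems,
                  paste0("patient(s) with samples in both classes: ",
                         paste(mixed, collapse = ", ")))
  }
  if (check_paths) {
    gone <- manifest$path[!vapply(manifest$path, file.exists, logical(1))]
    if (length(gone)) {
      problems <- c(problems, paste0("missing sample file(s): ",
                                     paste(gone, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("cohort validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Load a cohort of samples
#'
#' Reads every sample listed in the manifest (after validating the
#' metadata as one aggregated report) and assembles a `cyto_cohort`.
#'
#' @param manifest manifest data.frame or path to a manifest CSV.
#' @param panel a [marker_panel()] or path to a panel file.
#' @param verbose log per-class patient counts and total cells.
#' @return A `cyto_cohort`: list with `samples` (named list of
#'   [cell_matrix()]), `manifest`, and `panel`.
#' @export
load_cohort <- function(manifest, panel, verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(panel)) panel <- read_panel(panel)
  validate_manifest(manifest, check_paths = TRUE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    read_sample(manifest$path[i], panel, sample_id = manifest$sample_id[i])
  })
  names(samples) <- manifest$sample_id
  cohort <- structure(list(samples = samples, manifest = manifest, panel = panel),
                      class = "cyto_cohort")
  if (verbose) {
    pc <- patient_class_counts(manifest)
    message(sprintf("loaded cohort: %d samples, %d cells, patients per class {0:%d, 1:%d}",
                    nrow(manifest), total_cells(cohort), pc[["0"]], pc[["1"]]))
  }
  cohort
}

#' Per-class patient counts of a manifest
#' @param manifest manifest data.frame.
#' @return named vector with counts for classes "0" and "1".
#' @export
patient_class_counts <- function(manifest) {
  per_patient <- unique(manifest[, c("patient_id", "class")])
  c("0" = sum(per_patient$class == 0), "1" = sum(per_patient$class == 1))
}

#' Total cell count of a cohort
#' @param cohort a `cyto_cohort`.
#' @return integer total number of cells.
#' @export
total_cells <- function(cohort) {
  sum(vapply(cohort$samples, function(s) s$n_cells, numeric(1)))
}

#' @export
print.cyto_cohort <- function(x, ...) {
  cat(sprintf("cyto_cohort: %d samples, %d cells, %d analysis channels\n",
              length(x$samples), total_cells(x),
              length(panel_channels(x$panel))))
  invisible(x)
}

#' Write a cell matrix to CSV
#'
#' Plain comma-separated export (header of channel names, one cell per
#' row); with untransformed data this round-trips bit-exactly through
#' [read_sample()].
#'
#' @param cells a [cell_matrix()] or numeric matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  values <- if (inherits(cells, "cell_matrix")) cells$values else cells
  # %.17g guarantees doubles survive the text round trip bit-exactly
  txt <- matrix(sprintf("%.17g", values), nrow(values), ncol(values))
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  names(df) <- colnames(values)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}
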