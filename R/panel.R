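#' Construct a marker panel
#'
#' A marker panel declares, for every acquired channel, whether it is a
#' phenotypic (lineage) marker, a functional (e.g. phospho-signaling)
#' marker, or excluded from analysis (DNA, barcode, viability channels
#' that were only needed upstream), together with the per-channel
#' expression transform. Clustering and feature engineering use all
#' phenotypic *and* functional channels jointly, so frequency features
#' carry functional information; excluded channels are dropped at load
#' time.
#'
#' @param name character vector of channel names (unique, non-empty).
#' @param role one of `"phenotypic"`, `"functional"`, `"excluded"` per
#'   channel (recycled if length 1).
#' @param transform `"arcsinh"` (the mass-cytometry standard,
#'   `asinh(x / cofactor)`) or `"none"`, per channel.
#' @param cofactor positive arcsinh cofactor per channel; the CyTOF
#'   community default of 5 is used unless overridden. Ignored for
#'   `transform = "none"`.
#'
#' @return An object of class `marker_panel`: a data.frame with columns
#'   `name`, `role`, `transform`, `cofactor`.
#' @examples
#' marker_panel(c("CD3", "CD19", "pSTAT3", "DNA1"),
#'              role = c("phenotypic", "phenotypic", "functional", "excluded"))
#' @export
marker_panel <- function(name, role, transform = "arcsinh", cofactor = 5) {
  if (length(name) == 0) stop("panel must have at least one channel")
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("duplicate channel names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  role <- rep_len(as.character(role), length(name))
  transform <- rep_len(as.character(transform), length(name))
  cofactor <- rep_len(as.numeric(cofactor), length(name))
  bad_role <- setdiff(role, c("phenotypic", "functional", "excluded"))
  if (length(bad_role)) stop("unknown channel role: ", paste(bad_role, collapse = ", "))
  bad_tr <- setdiff(transform, c("arcsinh", "none"))
  if (length(bad_tr)) stop("unknown transform: ", paste(bad_tr, collapse = ", "))
  if (any(transform == "arcsinh" & (!is.finite(cofactor) | cofactor <= 0))) {
    stop("arcsinh cofactor must be a positive number")
  }
  if (!any(role == "phenotypic")) {
    stop("panel must contain at least one phenotypic channel")
  }
  panel <- data.frame(name = name, role = role, transform = transform,
                      cofactor = cofactor, stringsAsFactors = FALSE)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Read a marker panel from YAML or JSON
#'
#' Expects a top-level `channels` list whose entries have fields
#' `name`, `role` and optionally `transform` and `cofactor`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` panel file.
#' @return A [marker_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$channels)) stop("panel file must have a top-level 'channels' list")
  ch <- spec$channels
  marker_panel(
    name = vapply(ch, function(x) as.character(x$name), character(1)),
    role = vapply(ch, function(x) as.character(x$role), character(1)),
    transform = vapply(ch, function(x) {
      if (is.null(x$transform)) "arcsinh" else as.character(x$transform)
    }, character(1)),
    cofactor = vapply(ch, function(x) {
      if (is.null(x$cofactor)) 5 else as.numeric(x$cofactor)
    }, numeric(1))
  )
}

#' Write a marker panel to YAML
#' @param panel a [marker_panel()].
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  channels <- lapply(seq_len(nrow(panel)), function(i) {
    list(name = panel$name[i], role = panel$role[i],
         transform = panel$transform[i], cofactor = panel$cofactor[i])
  })
  yaml::write_yaml(list(channels = channels), path)
  invisible(path)
}

#' Channels used for analysis (non-excluded), in panel order
#' @param panel a [marker_panel()].
#' @param role optional filter: `"phenotypic"` or `"functional"`.
#' @return character vector of channel names.
#' @export
panel_channels <- function(panel, role = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  keep <- panel$role != "excluded"
  if (!is.null(role)) keep <- keep & panel$role == role
  panel$name[keep]
}

# Apply per-channel transforms to a cells x channels matrix whose columns
# are already restricted to non-excluded panel channels, in panel order.
apply_panel_transform <- function(values, panel) {
  kept <- panel[panel$role != "excluded", , drop = FALSE]
  stopifnot(ncol(values) == nrow(kept))
  for (j in seq_len(nrow(kept))) {
    if (kept$transform[j] == "arcsinh") {
      values[, j] <- asinh(values[, j] / kept$cofactor[j])
    }
  }
  colnames(values) <- kept$name
  values
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d channels (%d phenotypic, %d functional, %d excluded)\n",
              nrow(x), sum(x$role == "phenotypic"), sum(x$role == "functional"),
              sum(x$role == "excluded")))
  print.data.frame(x, ...)
  invisible(x)
}
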