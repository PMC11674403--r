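valid_zygosities <- c("MZ", "DZ", "UR")

#' The seven canonical intrinsic connectivity networks
#'
#' @return Character vector of network labels.
#' @export
canonical_icns <- function() {
  c("default mode", "frontoparietal", "dorsal attention",
    "salience/cingulo-opercular", "sensory-motor", "visual", "limbic")
}

#' A default region-to-network partition for synthetic data
#'
#' Assigns `n_regions` regions to the seven canonical networks in contiguous
#' blocks of near-equal size.
#'
#' @param n_regions number of regions.
#' @param networks network labels (default [canonical_icns()]).
#' @return Character vector of length `n_regions`.
#' @export
default_partition <- function(n_regions, networks = canonical_icns()) {
  sort(rep(networks, length.out = n_regions))
}

#' Write / read a cohort manifest
#'
#' Tab-separated file with columns `subject_id`, `pair_id`, `zygosity`,
#' `sex`, `age`.
#'
#' @param manifest data.frame with the columns above.
#' @param path file path.
#' @return `read_manifest` returns the validated data.frame.
#' @export
write_manifest <- function(manifest, path) {
  required <- c("subject_id", "pair_id", "zygosity", "sex", "age")
  stopifnot(all(required %in% names(manifest)))
  data.table::fwrite(manifest[required], path, sep = "\t")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  required <- c("subject_id", "pair_id", "zygosity", "sex", "age")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(m$zygosity), valid_zygosities)
  if (length(bad)) {
    stop("invalid zygosity label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(valid_zygosities, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Write / read a region-to-network partition
#'
#' JSON object mapping region names (or indices) to network labels.
#'
#' @param partition named character vector or list (region -> network).
#' @param path file path.
#' @param regions optional region names that must all be present on read.
#' @return `read_partition` returns a named character vector.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(as.list(partition), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, regions = NULL) {
  p <- unlist(jsonlite::read_json(path))
  if (!is.null(regions)) {
    missing <- setdiff(regions, names(p))
    if (length(missing)) {
      stop("partition is missing region(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    p <- p[regions]
  }
  p
}

#' Write / read an envelope store
#'
#' Directory layout: `meta.json` holding the sampling rate and band edges,
#' plus one tab-separated T x R matrix per subject per band at
#' `<band>/<subject_id>.tsv`. Numeric payloads round-trip losslessly.
#'
#' @param envelopes list by band of named lists of T x R matrices (the
#'   `envelopes` element of [generate_cohort()]).
#' @param fs envelope sampling rate.
#' @param path store directory (created if needed).
#' @param bands optional named list of [band_definition()]s for the metadata.
#' @return `read_envelope_store` returns `list(envelopes, fs, bands)`.
#' @export
write_envelope_store <- function(envelopes, fs, path, bands = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  band_meta <- lapply(names(envelopes), function(b) {
    bd <- bands[[b]] %||% canonical_bands()[[b]]
    list(name = b, low_hz = bd$low_hz %||% NA, high_hz = bd$high_hz %||% NA)
  })
  jsonlite::write_json(list(fs = fs, bands = band_meta),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  for (b in names(envelopes)) {
    bdir <- file.path(path, b)
    dir.create(bdir, showWarnings = FALSE)
    for (sid in names(envelopes[[b]])) {
      data.table::fwrite(as.data.frame(ts_matrix(envelopes[[b]][[sid]])),
                         file.path(bdir, paste0(sid, ".tsv")), sep = "\t")
    }
  }
  invisible(path)
}

#' @rdname write_envelope_store
#' @export
read_envelope_store <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not an envelope store (missing meta.json): ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  bands <- meta$bands$name
  envelopes <- lapply(bands, function(b) {
    files <- list.files(file.path(path, b), pattern = "\\.tsv$",
                        full.names = TRUE)
    mats <- lapply(files, function(f) as.matrix(data.table::fread(f)))
    names(mats) <- sub("\\.tsv$", "", basename(files))
    mats
  })
  names(envelopes) <- bands
  list(envelopes = envelopes, fs = meta$fs, bands = meta$bands)
}

#' Derive pair records from a manifest
#'
#' Groups a subject manifest into twin-pair records with pair-level
#' covariates (pair sex, absolute age difference).
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @return data.frame with `pair_id`, `subject_a`, `subject_b`, `zygosity`,
#'   `pair_sex`, `age_diff`.
#' @export
pairs_from_manifest <- function(manifest) {
  split_rows <- split(seq_len(nrow(manifest)), manifest$pair_id)
  bad <- names(split_rows)[vapply(split_rows, length, 0L) != 2L]
  if (length(bad)) {
    stop("each pair must have exactly two subjects; offending pair(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- do.call(rbind, lapply(split_rows, function(idx) {
    a <- manifest[idx[1], ]
    b <- manifest[idx[2], ]
    data.frame(pair_id = a$pair_id, subject_a = a$subject_id,
               subject_b = b$subject_id, zygosity = a$zygosity,
               pair_sex = a$sex, age_diff = abs(a$age - b$age),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows[order(match(rows$pair_id, manifest$pair_id)), , drop = FALSE]
}
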