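#' Read / write an expression matrix
#'
#' Tab-separated text, genes as rows, samples as columns, header row of
#' sample ids.
#'
#' @param path File path.
#' @return `read_expression()`: numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_expression
#' @param mat Gene-by-sample matrix.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated with columns `sample_id`, `tissue`, `histology` and the
#' mutation flags `CTNNB1`, `NFE2L2`, `TERT`.
#'
#' @param path File path.
#' @return `read_metadata()`: a data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("CTNNB1", "NFE2L2", "TERT"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname read_metadata
#' @param metadata Metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a drug panel
#'
#' Structured YAML: a list of entries with `name`, `class_label` and
#' `targets` (each with `species` and `kD_nM`).
#'
#' @param path File path.
#' @return `read_panel()`: named list of [drug_spec()] objects.
#' @export
read_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  drugs <- lapply(raw, function(d) {
    targets <- stats::setNames(
      vapply(d$targets, function(t) as.numeric(t$kD_nM), 0),
      vapply(d$targets, function(t) t$species, ""))
    drug_spec(d$name, targets, d$class_label %||% "")
  })
  stats::setNames(drugs, vapply(drugs, `[[`, "", "name"))
}

#' @rdname read_panel
#' @param drugs List of [drug_spec()] objects.
#' @export
write_panel <- function(drugs, path) {
  yaml::write_yaml(lapply(unname(drugs), function(d) {
    list(name = d$name, class_label = d$class_label,
         targets = lapply(seq_along(d$targets), function(i)
           list(species = names(d$targets)[i],
                kD_nM = unname(d$targets[i]))))
  }), path, precision = 15L)
  invisible(path)
}

#' Write screen results
#'
#' Writes the per-(sample, drug) summary as CSV and the run manifest (seed,
#' configuration hash, dropped-run count) as JSON next to it.
#'
#' @param screen A `ScreenResult`.
#' @param path CSV output path; the manifest goes to the same path with a
#'   `.manifest.json` suffix.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  utils::write.csv(screen$results, path, row.names = FALSE)
  jsonlite::write_json(screen$manifest,
                       paste0(sub("\\.csv$", "", path), ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write viability plates
#'
#' Long CSV with columns `model_id`, `class`, `compound`, `dose`,
#' `dose_unit`, `replicate`, `viability`; one [plate_assay()] per
#' (model_id, compound) pair.
#'
#' @param path File path.
#' @return `read_plates()`: list of `PlateAssay` objects.
#' @export
read_plates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[, c("model_id", "compound")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$model_id == keys$model_id[i] & df$compound == keys$compound[i], ]
    doses <- sort(unique(sub$dose))
    reps <- sort(unique(sub$replicate))
    v <- matrix(NA_real_, length(reps), length(doses))
    for (j in seq_len(nrow(sub)))
      v[match(sub$replicate[j], reps), match(sub$dose[j], doses)] <- sub$viability[j]
    plate_assay(doses, v, compound = keys$compound[i],
                model_id = keys$model_id[i], class = sub$class[1],
                dose_unit = sub$dose_unit[1])
  })
}

#' @rdname read_plates
#' @param plates List of `PlateAssay` objects (or a single one).
#' @export
write_plates <- function(plates, path) {
  if (inherits(plates, "PlateAssay")) plates <- list(plates)
  rows <- do.call(rbind, lapply(plates, function(p) {
    data.frame(model_id = p$model_id, class = p$class, compound = p$compound,
               dose = rep(p$doses, each = nrow(p$viability)),
               dose_unit = p$dose_unit,
               replicate = rep(seq_len(nrow(p$viability)), length(p$doses)),
               viability = as.vector(p$viability))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a synergy grid
#'
#' Long CSV with columns `dose_a`, `dose_b`, `inhibition` describing the
#' 4x4 matrix.
#'
#' @param path File path.
#' @return `read_synergy_grid()`: list with `inhibition`, `doses_a`,
#'   `doses_b`.
#' @export
read_synergy_grid <- function(path) {
  df <- utils::read.csv(path)
  da <- sort(unique(df$dose_a)); db <- sort(unique(df$dose_b))
  m <- matrix(NA_real_, length(da), length(db))
  for (i in seq_len(nrow(df)))
    m[match(df$dose_a[i], da), match(df$dose_b[i], db)] <- df$inhibition[i]
  list(inhibition = m, doses_a = da, doses_b = db)
}

#' @rdname read_synergy_grid
#' @param grid List with `inhibition`, `doses_a`, `doses_b`.
#' @export
write_synergy_grid <- function(grid, path) {
  df <- expand.grid(dose_a = grid$doses_a, dose_b = grid$doses_b)
  df$inhibition <- as.vector(grid$inhibition)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
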