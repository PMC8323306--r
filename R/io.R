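# Delimited-text I/O with schema validation. All tabular artifacts are
# plain tab-separated text with one header row; unit declarations travel
# in '#' comment lines so files stay self-describing and auditable.

#' Read and validate a delimited table
#'
#' @param path File path (tab-separated, '#' comments allowed).
#' @param columns Named character vector declaring required columns and
#'   their types (`"character"` or `"numeric"`).
#' @param id_column Optional column that must not contain duplicates.
#' @return data.frame.
#' @export
read_table <- function(path, columns = NULL, id_column = NULL) {
  if (!file.exists(path)) .verror("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    missing <- setdiff(names(columns), names(df))
    if (length(missing))
      .verror("missing column(s) in ", path, ": ",
              paste(missing, collapse = ", "))
    for (cn in names(columns)) {
      if (columns[[cn]] == "numeric") {
        bad <- which(!is.na(df[[cn]]) & is.na(suppressWarnings(
          as.numeric(df[[cn]]))))
        if (length(bad))
          .verror("non-numeric value in ", path, ", column '", cn,
                  "', row ", bad[1])
        df[[cn]] <- as.numeric(df[[cn]])
      }
    }
  }
  if (!is.null(id_column)) {
    dup <- df[[id_column]][duplicated(df[[id_column]])]
    if (length(dup))
      .verror("duplicate ", id_column, " in ", path, ": ",
              paste(unique(dup), collapse = ", "))
  }
  df
}

#' Write a delimited table
#'
#' @param df data.frame.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written
#'   with a leading '#').
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.verror <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("mitoflex_validation_error", "error")))
}

#' Write an omics table to a directory
#'
#' Emits `<prefix>_values.tsv` (analyte column + one column per sample),
#' `<prefix>_samples.tsv` and, when class annotation is present,
#' `<prefix>_classes.tsv`. Group labels live only in the sample sheet.
#'
#' @param tab An [omics_table()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_omics_table <- function(tab, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vpath <- file.path(dir, paste0(prefix, "_values.tsv"))
  spath <- file.path(dir, paste0(prefix, "_samples.tsv"))
  vals <- data.frame(analyte = rownames(tab$values), tab$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_table(vals, vpath)
  write_table(tab$samples, spath)
  paths <- c(vpath, spath)
  if (!is.null(tab$classes)) {
    cpath <- file.path(dir, paste0(prefix, "_classes.tsv"))
    write_table(data.frame(analyte = names(tab$classes),
                           class = unname(tab$classes)), cpath)
    paths <- c(paths, cpath)
  }
  invisible(paths)
}

#' Read an omics table written by [write_omics_table()]
#'
#' @param values_path,samples_path,classes_path File paths; classes are
#'   optional.
#' @return An [omics_table()].
#' @export
read_omics_table <- function(values_path, samples_path,
                             classes_path = NULL) {
  vals <- read_table(values_path, columns = c(analyte = "character"),
                     id_column = "analyte")
  m <- as.matrix(vals[, -1, drop = FALSE])
  if (!is.numeric(m)) .verror("non-numeric intensities in ", values_path)
  rownames(m) <- vals$analyte
  samples <- read_table(samples_path,
                        columns = c(sample = "character",
                                    age = "character", diet = "character"),
                        id_column = "sample")
  classes <- NULL
  if (!is.null(classes_path)) {
    cl <- read_table(classes_path, columns = c(analyte = "character",
                                               class = "character"),
                     id_column = "analyte")
    classes <- stats::setNames(cl$class, cl$analyte)
  }
  omics_table(m, samples, classes)
}

#' Write OGTT series in long format
#'
#' Columns: `animal`, `time_min`, `analyte` (glucose/insulin), `value`,
#' `unit`.
#'
#' @param series_list Named list of [ogtt_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ogtt <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    g <- data.frame(animal = s$animal, time_min = s$glucose_times,
                    analyte = "glucose", value = s$glucose, unit = "mM")
    if (is.null(s$insulin)) return(g)
    rbind(g, data.frame(animal = s$animal, time_min = s$insulin_times,
                        analyte = "insulin", value = s$insulin,
                        unit = s$insulin_unit))
  }))
  write_table(rows, path)
}

#' Read OGTT series from long format
#'
#' @param path File written by [write_ogtt()].
#' @return Named list of [ogtt_series()].
#' @export
read_ogtt <- function(path) {
  df <- read_table(path, columns = c(animal = "character",
                                     time_min = "numeric",
                                     analyte = "character",
                                     value = "numeric",
                                     unit = "character"))
  out <- lapply(split(df, df$animal), function(d) {
    g <- d[d$analyte == "glucose", ]
    g <- g[order(g$time_min), ]
    i <- d[d$analyte == "insulin", ]
    i <- i[order(i$time_min), ]
    ogtt_series(d$animal[1], g$time_min, g$value,
                if (nrow(i)) i$time_min else NULL,
                if (nrow(i)) i$value else NULL,
                insulin_unit = if (nrow(i)) i$unit[1] else "mU/L")
  })
  out[unique(df$animal)]
}
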