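#' Construct an in-memory protein-groups table
#'
#' The in-memory form of a MaxQuant-dialect `proteinGroups.txt`: one row per
#' protein group with identifier columns, the unique-peptide count, the three
#' quality flags, and one LFQ intensity column per sample. Missing
#' intensities are `NA` in memory (MaxQuant writes them as 0 on disk).
#'
#' @param ids character vector of protein IDs.
#' @param gene_names character vector of gene names.
#' @param unique_peptides integer vector of unique peptide counts.
#' @param flags data.frame with logical columns `only_identified_by_site`,
#'   `reverse`, `potential_contaminant`.
#' @param intensities numeric matrix (proteins x samples) of LFQ intensities
#'   with `NA` for missing; column names are the sample names.
#' @return data.frame of class `protein_groups` with attribute `samples`.
#' @export
protein_groups <- function(ids, gene_names, unique_peptides, flags,
                           intensities) {
  n <- length(ids)
  stopifnot(is.matrix(intensities), nrow(intensities) == n,
            !is.null(colnames(intensities)))
  need <- c("only_identified_by_site", "reverse", "potential_contaminant")
  if (!all(need %in% names(flags))) {
    stop_param("flags must contain columns: ", paste(need, collapse = ", "))
  }
  if (any(intensities <= 0, na.rm = TRUE)) {
    stop_param("LFQ intensities must be positive or missing (NA)")
  }
  df <- data.frame(ids = as.character(ids),
                   gene_name = as.character(gene_names),
                   unique_peptides = as.integer(unique_peptides),
                   only_identified_by_site = as.logical(flags$only_identified_by_site),
                   reverse = as.logical(flags$reverse),
                   potential_contaminant = as.logical(flags$potential_contaminant),
                   stringsAsFactors = FALSE)
  samples <- colnames(intensities)
  for (s in samples) df[[paste0("lfq.", s)]] <- as.numeric(intensities[, s])
  attr(df, "samples") <- samples
  class(df) <- c("protein_groups", "data.frame")
  df
}

#' Extract the LFQ intensity matrix from a protein-groups table
#'
#' @param table a [protein_groups()] table.
#' @return numeric matrix (proteins x samples), `NA` for missing.
#' @export
intensity_matrix <- function(table) {
  stopifnot(inherits(table, "protein_groups"))
  samples <- attr(table, "samples")
  m <- as.matrix(as.data.frame(table)[paste0("lfq.", samples)])
  colnames(m) <- samples
  rownames(m) <- table$ids
  m
}

#' Read a MaxQuant-dialect proteinGroups.txt
#'
#' Tab-separated with columns `LFQ intensity <sample>` for each declared
#' sample, `Unique peptides`, and the flag columns `Only identified by
#' site`, `Reverse`, `Potential contaminant` (`"+"` = flagged). Zero LFQ
#' intensities are converted to missing (`NA`), following the MaxQuant
#' convention that 0 means "not quantified".
#'
#' @param path path to the tab-separated file.
#' @param sample_names character vector of sample names to read.
#' @return a [protein_groups()] table.
#' @export
read_protein_groups <- function(path, sample_names) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  lfq_cols <- paste("LFQ intensity", sample_names)
  need <- c("Protein IDs", "Gene names", "Unique peptides",
            "Only identified by site", "Reverse", "Potential contaminant",
            lfq_cols)
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop_format("missing required column(s): ", paste(absent, collapse = ", "))
  }
  inten <- as.matrix(df[lfq_cols])
  if (any(!is.finite(inten) & !is.na(inten)) || any(inten < 0, na.rm = TRUE)) {
    stop_format("LFQ intensities must be finite and non-negative")
  }
  inten[inten == 0] <- NA_real_  # MaxQuant zero-means-missing
  colnames(inten) <- sample_names
  protein_groups(
    ids = df[["Protein IDs"]],
    gene_names = df[["Gene names"]],
    unique_peptides = df[["Unique peptides"]],
    flags = data.frame(
      only_identified_by_site = df[["Only identified by site"]] == "+",
      reverse = df[["Reverse"]] == "+",
      potential_contaminant = df[["Potential contaminant"]] == "+"
    ),
    intensities = inten
  )
}

#' Write a protein-groups table in the MaxQuant dialect
#'
#' Missing intensities are written as 0, flags as `"+"`/empty.
#'
#' @param table a [protein_groups()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path) {
  stopifnot(inherits(table, "protein_groups"))
  samples <- attr(table, "samples")
  inten <- intensity_matrix(table)
  inten[is.na(inten)] <- 0
  out <- data.frame(`Protein IDs` = table$ids,
                    `Gene names` = table$gene_name,
                    `Unique peptides` = table$unique_peptides,
                    `Only identified by site` = ifelse(table$only_identified_by_site, "+", ""),
                    Reverse = ifelse(table$reverse, "+", ""),
                    `Potential contaminant` = ifelse(table$potential_contaminant, "+", ""),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in samples) out[[paste("LFQ intensity", s)]] <- inten[, s]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an absorbance plate table
#'
#' Tab-separated columns `well`, `role` (`test` or `media_only`), `A570`,
#' `A600`.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `plate_table`.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop_format("plate file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("well", "role", "A570", "A600")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop_format("plate table missing column(s): ", paste(absent, collapse = ", "))
  }
  if (!all(df$role %in% c("test", "media_only"))) {
    stop_format("plate roles must be 'test' or 'media_only'")
  }
  if (any(!is.finite(df$A570)) || any(!is.finite(df$A600))) {
    stop_format("absorbances must be finite")
  }
  class(df) <- c("plate_table", "data.frame")
  df
}

#' Write an absorbance plate table
#'
#' @param plate a `plate_table` data.frame (columns `well`, `role`, `A570`,
#'   `A600`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  utils::write.table(as.data.frame(plate)[c("well", "role", "A570", "A600")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
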