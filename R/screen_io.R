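# Sentinel gene name carried by non-targeting guides in on-disk tables, so the
# two-column (guide, gene) layout stays mandatory.
NT_SENTINEL <- "NonTargeting"

#' Construct and validate a guide library
#'
#' A guide library maps each guide (sgRNA) to its target gene and a control
#' category. Non-targeting guides carry the sentinel gene
#' \code{"NonTargeting"}.
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param gene character vector of target gene symbols (sentinel for
#'   non-targeting guides).
#' @param category one of \code{"targeting"}, \code{"non_targeting"},
#'   \code{"pan_essential"} per guide.
#' @return A \code{data.frame} of class \code{guide_library}.
#' @export
guide_library <- function(guide_id, gene, category) {
  lib <- data.frame(guide_id = as.character(guide_id),
                    gene = as.character(gene),
                    category = as.character(category),
                    stringsAsFactors = FALSE)
  validate_guide_library(lib)
}

#' @rdname guide_library
#' @param lib a data.frame with columns \code{guide_id}, \code{gene},
#'   \code{category}.
#' @export
validate_guide_library <- function(lib) {
  req <- c("guide_id", "gene", "category")
  miss <- setdiff(req, names(lib))
  if (length(miss))
    stop("guide library missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(lib$guide_id))
    stop("duplicate guide_id(s): ",
         paste(unique(lib$guide_id[duplicated(lib$guide_id)])[1:5], collapse = ", "))
  ok_cat <- c("targeting", "non_targeting", "pan_essential")
  bad <- setdiff(unique(lib$category), ok_cat)
  if (length(bad))
    stop("unknown guide category: ", paste(bad, collapse = ", "))
  tg <- lib$category %in% c("targeting", "pan_essential")
  if (any(tg & (is.na(lib$gene) | lib$gene == "" | lib$gene == NT_SENTINEL)))
    stop("targeting/pan_essential guides must carry a non-empty gene symbol")
  lib$gene[lib$category == "non_targeting"] <- NT_SENTINEL
  # a gene's guides must all share one category
  mixed <- tapply(lib$category[tg], lib$gene[tg],
                  function(x) length(unique(x)) > 1L)
  if (any(mixed))
    stop("gene(s) with mixed guide categories: ",
         paste(names(mixed)[mixed][1:5], collapse = ", "))
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Construct and validate a sample sheet
#'
#' Each drug-treated sample must have a matching vehicle sample from the same
#' cell line, and a cell line's group (case vs outgroup) must be constant.
#'
#' @param df data.frame with columns \code{sample_id}, \code{cell_line},
#'   \code{condition} (\code{"drug"}/\code{"vehicle"}), \code{drug} (empty for
#'   vehicle), \code{group} (\code{"case"}/\code{"outgroup"}),
#'   \code{drug_class} (\code{"dna_damage"}/\code{"other"}).
#' @return validated \code{data.frame} of class \code{sample_sheet}.
#' @export
validate_sample_sheet <- function(df) {
  req <- c("sample_id", "cell_line", "condition", "drug", "group", "drug_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  for (col in req) df[[col]] <- as.character(df[[col]])
  df$drug[is.na(df$drug)] <- ""
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s) in sample sheet")
  if (!all(df$condition %in% c("drug", "vehicle")))
    stop("condition must be 'drug' or 'vehicle'")
  if (!all(df$group %in% c("case", "outgroup")))
    stop("group must be 'case' or 'outgroup'")
  if (!all(df$drug_class %in% c("dna_damage", "other")))
    stop("drug_class must be 'dna_damage' or 'other'")
  if (any(df$condition == "drug" & df$drug == ""))
    stop("drug samples must name their drug")
  ngrp <- tapply(df$group, df$cell_line, function(x) length(unique(x)))
  if (any(ngrp > 1L))
    stop("group must be constant within cell line: ",
         paste(names(ngrp)[ngrp > 1L], collapse = ", "))
  dr <- df[df$condition == "drug", , drop = FALSE]
  veh_lines <- unique(df$cell_line[df$condition == "vehicle"])
  orphan <- !(dr$cell_line %in% veh_lines)
  if (any(orphan))
    stop("drug sample(s) without a vehicle partner: ",
         paste(sprintf("(%s, %s)", dr$cell_line[orphan], dr$drug[orphan]),
               collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Construct a screen-counts object
#'
#' @param counts non-negative integer matrix, guides in rows, samples in
#'   columns; dimnames give guide and sample ids.
#' @param gene optional per-guide gene vector (from the count file's second
#'   column); kept for writing.
#' @param library optional \code{guide_library} to cross-check guide ids and
#'   gene assignments against.
#' @return list of class \code{screen_counts} with elements \code{counts},
#'   \code{guides}, \code{samples}, \code{gene}.
#' @export
screen_counts <- function(counts, gene = NULL, library = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts matrix must carry guide (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate guide ids in count matrix")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(gene)) gene <- rep(NA_character_, nrow(counts))
  if (!is.null(library)) {
    unknown <- setdiff(rownames(counts), library$guide_id)
    if (length(unknown))
      stop("guide id(s) absent from library: ",
           paste(unknown[seq_len(min(5, length(unknown)))], collapse = ", "))
    lg <- library$gene[match(rownames(counts), library$guide_id)]
    have <- !is.na(gene)
    if (any(have & gene != lg))
      stop("gene column disagrees with library for guide(s): ",
           paste(rownames(counts)[have & gene != lg][1:5], collapse = ", "))
    gene <- lg
  }
  structure(list(counts = counts, guides = rownames(counts),
                 samples = colnames(counts), gene = gene),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d guides x %d samples, total reads %.3g\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts))))
  invisible(x)
}

#' Read a MAGeCK-style count table
#'
#' Expects a TSV whose first two columns are the guide id and gene symbol,
#' followed by one integer column per sample. Guide and sample order is
#' preserved exactly.
#'
#' @param path file path.
#' @param library optional \code{guide_library} to cross-check against.
#' @return a \code{screen_counts} object.
#' @export
read_counts <- function(path, library = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L)
    stop("count table needs guide, gene and at least one sample column: ", path)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate guide id at row(s): ",
         paste(which(duplicated(df[[1L]]))[1:5], collapse = ", "))
  samp <- names(df)[-(1:2)]
  mat <- matrix(NA_real_, nrow(df), length(samp),
                dimnames = list(df[[1L]], samp))
  for (j in seq_along(samp)) {
    v <- suppressWarnings(as.numeric(df[[j + 2L]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf("non-integer or negative count at row %d, column '%s'",
                   bad[1L], samp[j]))
    mat[, j] <- v
  }
  storage.mode(mat) <- "integer"
  screen_counts(mat, gene = df[[2L]], library = library)
}

#' Write a MAGeCK-style count table
#' @param x a \code{screen_counts} object.
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  gene <- x$gene
  gene[is.na(gene)] <- NT_SENTINEL
  df <- data.frame(sgRNA = x$guides, gene = gene, x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a guide library TSV (guide_id, gene, category)
#' @param path file path.
#' @return a \code{guide_library}.
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  validate_guide_library(df)
}

#' @rdname read_library
#' @param lib a \code{guide_library}.
#' @export
write_library <- function(lib, path) {
  utils::write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet CSV
#' @param path file path.
#' @return validated \code{sample_sheet}.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a \code{sample_sheet}.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes within
#' a set are collapsed (first occurrence kept).
#'
#' @param path file path.
#' @return named list of character vectors (class \code{gene_set_collection}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("GMT line %d (set '%s') has no genes", i, f[1L]))
    sets[[f[1L]]] <- genes
  }
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' Tables are written UTF-8, tab-separated, '.' decimal, preceded by a single
#' comment line recording the package version and a hash of the run
#' configuration so outputs are traceable to their settings.
#'
#' @param table data.frame to write.
#' @param path output path.
#' @param config optional R object (typically the run config) hashed into the
#'   header comment.
#' @export
write_results <- function(table, path, config = NULL) {
  ver <- as.character(utils::packageVersion("chemosens"))
  h <- if (is.null(config)) "none" else config_hash(config)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# chemosens %s config_hash=%s", ver, h), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
}

# md5 of the deparsed config; stable across sessions for plain lists
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

#' Cross-file consistency validation
#'
#' Checks that counts, library and sample sheet agree: every counted guide is
#' in the library, every counted sample is on the sheet, and the sheet itself
#' validates.
#'
#' @param counts a \code{screen_counts}.
#' @param library a \code{guide_library}.
#' @param sheet a \code{sample_sheet}.
#' @return invisibly \code{TRUE}; stops with an informative error otherwise.
#' @export
validate_screen <- function(counts, library, sheet) {
  library <- validate_guide_library(as.data.frame(library))
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  unknown <- setdiff(counts$guides, library$guide_id)
  if (length(unknown))
    stop("counted guide(s) absent from library: ",
         paste(unknown[1:5], collapse = ", "))
  missing_samp <- setdiff(counts$samples, sheet$sample_id)
  if (length(missing_samp))
    stop("counted sample(s) absent from sample sheet: ",
         paste(missing_samp[1:5], collapse = ", "))
  invisible(TRUE)
}
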