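# FASTA with 80-column wrapping; ids written verbatim
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1, nchar(s), 80),
                         pmin(seq(1, nchar(s), 80) + 79, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  setNames(toupper(vapply(as.character(x), paste, "", collapse = "")),
           names(x))
}

#' Read/write a reference panel as FASTA
#'
#' Header convention: `>refID|Genus_species|groupID`.
#'
#' @param panel a [reference_panel()].
#' @param path file path.
#' @return `write_panel_fasta` the path (invisibly); `read_panel_fasta` a
#'   `reference_panel` (sister map re-derived from identities).
#' @export
write_panel_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  rec <- panel$records
  write_fasta(setNames(rec$seq, paste(rec$id, rec$species, rec$group,
                                      sep = "|")), path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(vapply(parts, length, 0L) != 3))
    stop("panel FASTA headers must be 'refID|Genus_species|groupID'")
  reference_panel(data.frame(
    id = vapply(parts, `[`, "", 1),
    species = vapply(parts, `[`, "", 2),
    group = vapply(parts, `[`, "", 3),
    seq = unname(seqs), stringsAsFactors = FALSE))
}

#' Read/write plate fluorescence data as CSV
#'
#' Long format: plate_id, well, role, sample_id, dye, cycle, delta_rn.
#'
#' @param plates long plate data.frame.
#' @param path file path.
#' @export
write_plate_csv <- function(plates, path) {
  write.csv(plates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(sample_id = "character"))
  need <- c("plate_id", "well", "role", "sample_id", "dye", "cycle",
            "delta_rn")
  if (!all(need %in% names(x)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  x$sample_id[x$sample_id == ""] <- NA_character_
  x
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
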