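#' Curated Pfam-to-pathway map for methanogenesis-related enzymes
#'
#' Returns the package's curated default map linking Pfam protein-family
#' accessions to the acetyl-CoA pathway, methanogenesis, and the
#' Wood-Ljungdahl pathway. The map ships as an editable TSV
#' (`system.file("extdata", "methanogenesis_pfams.tsv", package =
#' "metacompare")`) and any table with columns `pfam_acc` and `pathway`
#' can be supplied in its place.
#'
#' @param path optional TSV with columns `pfam_acc`, `pathway` (and
#'   optionally `enzyme`); defaults to the shipped map.
#' @return data.frame with columns `pfam_acc`, `pathway`, `enzyme`.
#' @export
methanogenesis_pathway_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "methanogenesis_pfams.tsv",
                        package = "metacompare")
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pfam_acc", "pathway") %in% names(df)))
    mc_stop("pathway map needs columns 'pfam_acc' and 'pathway'")
  if (!nrow(df)) mc_stop("pathway map is empty")
  if (!("enzyme" %in% names(df))) df$enzyme <- NA_character_
  df
}

#' Compare archaeal methanogenesis gene content between two samples
#'
#' Filters each sample's functional records to those assigned to the
#' superkingdom *Archaea* and to Pfam families present in the pathway
#' map, counts reads per family, and scales each sample's counts to the
#' smallest dataset (`N_min / total`). Records lacking a superkingdom
#' assignment are skipped; their number is reported via a warning and in
#' the `skipped` attribute.
#'
#' @param a,b data.frames of functional records (`read_id`, `pfam_acc`,
#'   `superkingdom`, `evalue`).
#' @param pathway_map data.frame from [methanogenesis_pathway_map()].
#' @param totals integer vector of the two datasets' totals, `c(total_a,
#'   total_b)`.
#' @return data.frame with columns `pathway`, `pfam_acc`, `enzyme`,
#'   `count_a`, `count_b` (normalized counts), one row per map family
#'   (zero when unobserved), ordered by pathway then accession; attribute
#'   `skipped` holds the per-sample skipped-record counts.
#' @export
methanogenesis_comparison <- function(a, b,
                                      pathway_map = methanogenesis_pathway_map(),
                                      totals) {
  if (length(totals) != 2L || any(totals <= 0))
    mc_stop("'totals' must be two positive dataset sizes")
  n_min <- min(totals)
  count_one <- function(recs) {
    if (!("superkingdom" %in% names(recs))) {
      skipped <- nrow(recs)
      recs <- recs[0, , drop = FALSE]
    } else {
      skipped <- sum(is.na(recs$superkingdom) | !nzchar(recs$superkingdom))
      recs <- recs[!is.na(recs$superkingdom) & recs$superkingdom == "Archaea", ,
                   drop = FALSE]
    }
    recs <- recs[recs$pfam_acc %in% pathway_map$pfam_acc, , drop = FALSE]
    list(counts = table(factor(recs$pfam_acc,
                               levels = pathway_map$pfam_acc)),
         skipped = skipped)
  }
  ra <- count_one(a); rb <- count_one(b)
  if (ra$skipped + rb$skipped > 0)
    warning(sprintf("skipped %d record(s) lacking a superkingdom assignment",
                    ra$skipped + rb$skipped))
  out <- data.frame(pathway = pathway_map$pathway,
                    pfam_acc = pathway_map$pfam_acc,
                    enzyme = pathway_map$enzyme,
                    count_a = as.numeric(ra$counts) * (n_min / totals[1L]),
                    count_b = as.numeric(rb$counts) * (n_min / totals[2L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pathway, out$pfam_acc), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(a = ra$skipped, b = rb$skipped)
  out
}
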