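#' Download GenBank records from NCBI
#'
#' Fetches flat-file records via NCBI E-utilities (efetch) and parses them
#' with [read_genbank()]. Requires network access.
#'
#' @param accessions character vector of accession numbers (for the seven
#'   deposited genomes this analysis emulates: PQ367224-PQ367230)
#' @param dest optional path to keep the downloaded flat file
#' @param timeout seconds before the download attempt fails
#' @return list of [mitogenome()] records
#' @export
fetch_genbank <- function(accessions, dest = tempfile(fileext = ".gb"),
                          timeout = 60) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=gbwithparts&retmode=text&id=",
    paste(accessions, collapse = ","))
  old <- options(timeout = timeout)
  on.exit(options(old))
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  read_genbank(dest)
}
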