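# Intron extraction, insertion-position mapping onto a reference species,
# tolerance clustering into intron position sets (IPSs), and flanking
# sequence profiling.

#' Extract intron records from an annotated genome
#'
#' One row per intron feature. `local_pos` is the number of host-gene
#' coding (exonic) nucleotides 5' of the insertion point — the coordinate
#' IPS analysis works in. Phase is `local_pos mod 3` for protein-coding
#' hosts (0 = between codons) and `NA` for rRNA hosts. Flanks are taken
#' from the spliced exonic sequence (15 nt each side; shorter at gene ends
#' and flagged via `flank_truncated`).
#'
#' @param record an annotated [mitogenome()]
#' @param flank_width exonic flank width in nt
#' @return tibble: `species_id`, `host_gene`, `host_category`, `ordinal`,
#'   `start`, `end`, `length`, `local_pos`, `phase`, `flank_up`,
#'   `flank_down`, `flank_truncated`, `first_dint`, `has_heg`
#' @export
extract_introns <- function(record, flank_width = 15) {
  stopifnot(is_mitogenome(record))
  feats <- record$features
  intr <- feats[feats$category == "intron", ]
  out <- list()
  if (nrow(intr) == 0) return(intron_tibble())
  hegs <- feats[feats$category == "heg", ]
  for (host in unique(intr$parent)) {
    if (is.na(host)) {
      warning(record$id, ": intron without resolvable parent skipped")
      next
    }
    host_row <- feats[feats$gene_name == host &
                        feats$category %in% c("core_pcg", "rrna"), ]
    if (nrow(host_row) == 0) {
      warning(record$id, ": intron parent ", host, " not annotated; skipped")
      next
    }
    cds <- extract_cds(record, host, translate = FALSE)
    sub <- intr[!is.na(intr$parent) & intr$parent == host, ]
    starts <- vapply(sub$segments, feature_start, numeric(1))
    ord <- if (cds$strand == "+") order(starts) else order(-starts)
    sub <- sub[ord, ]
    offs <- cds$exon_offsets
    if (length(offs) != nrow(sub)) {
      warning(record$id, ": ", host, " has ", nrow(sub),
              " intron features but ", length(offs),
              " exon gaps; using genomic gaps")
      offs <- offs[seq_len(nrow(sub))]
    }
    is_pcg <- host_row$category[1] == "core_pcg"
    spl <- cds$spliced_seq
    for (i in seq_len(nrow(sub))) {
      lp <- offs[i]
      if (is.na(lp)) next
      seg <- sub$segments[[i]]
      a <- min(seg$start); b <- max(seg$end)
      iseq <- segment_seq(record$sequence, a, b, cds$strand)
      fu <- substr(spl, max(1, lp - flank_width + 1), lp)
      fd <- substr(spl, lp + 1, min(nchar(spl), lp + flank_width))
      has_heg <- any(vapply(hegs$segments, function(hs) {
        all(hs$start >= a & hs$end <= b)
      }, logical(1)))
      out[[length(out) + 1]] <- tibble::tibble(
        species_id = record$id, host_gene = host,
        host_category = host_row$category[1], ordinal = i,
        start = a, end = b, length = b - a,
        local_pos = lp,
        phase = if (is_pcg) lp %% 3 else NA_integer_,
        flank_up = fu, flank_down = fd,
        flank_truncated = nchar(fu) < flank_width | nchar(fd) < flank_width,
        first_dint = substr(iseq, 1, 2),
        has_heg = has_heg
      )
    }
  }
  if (length(out) == 0) return(intron_tibble())
  dplyr::bind_rows(out)
}

#' @noRd
intron_tibble <- function() {
  tibble::tibble(species_id = character(0), host_gene = character(0),
                 host_category = character(0), ordinal = integer(0),
                 start = integer(0), end = integer(0), length = integer(0),
                 local_pos = integer(0), phase = integer(0),
                 flank_up = character(0), flank_down = character(0),
                 flank_truncated = logical(0), first_dint = character(0),
                 has_heg = logical(0))
}

#' Map a coding-coordinate insertion position onto a reference sequence
#'
#' For protein-coding hosts a codon-aware alignment is used; for rRNA
#' hosts a nucleotide alignment. The returned reference position is the
#' number of reference nucleotides aligned strictly 5' of the insertion
#' point; insertions facing a reference gap map to the nearest 5'
#' reference nucleotide.
#'
#' @param local_pos insertion position in query coding nucleotides
#' @param query_cds,ref_cds `coding_sequence` objects of the same gene
#' @param codon_aware use protein-level alignment (TRUE for PCGs)
#' @return integer reference position
#' @export
map_to_reference <- function(local_pos, query_cds, ref_cds,
                             codon_aware = TRUE) {
  if (codon_aware) {
    al <- align_codon_aware(query_cds, ref_cds)
    cols <- al$columns
    qc <- local_pos %/% 3 + 1L   # query codon containing/following the point
    r <- local_pos %% 3
    col <- which(!is.na(cols$idx_a) & cols$idx_a == qc)
    if (length(col) == 0) {      # insertion past the aligned query end
      return(3L * sum(!is.na(cols$idx_b)))
    }
    nb <- sum(!is.na(cols$idx_b[seq_len(col - 1)]))
    ref_pos <- 3L * nb + if (!is.na(cols$idx_b[col])) r else 0L
    return(as.integer(ref_pos))
  }
  cols <- align_nucleotide(query_cds, ref_cds)
  qn <- local_pos + 1L           # first query nt after the insertion
  col <- which(!is.na(cols$idx_a) & cols$idx_a == qn)
  if (length(col) == 0) return(sum(!is.na(cols$idx_b)))
  as.integer(sum(!is.na(cols$idx_b[seq_len(col - 1)])))
}

#' Map all introns of a cohort onto the reference species
#'
#' @param records list of annotated [mitogenome()] records
#' @param introns combined [extract_introns()] tibble for the cohort
#'   (computed when `NULL`)
#' @param reference species id of the reference genome (its own introns map
#'   to their `local_pos` unchanged)
#' @return `introns` with `ref_pos` and `indirect` columns added
#' @export
map_introns_to_reference <- function(records, introns = NULL, reference) {
  ids <- purrr::map_chr(records, "id")
  stopifnot(reference %in% ids)
  if (is.null(introns)) {
    introns <- dplyr::bind_rows(purrr::map(records, extract_introns))
  }
  if (nrow(introns) == 0) {
    introns$ref_pos <- integer(0); introns$indirect <- logical(0)
    return(introns)
  }
  ref_rec <- records[[which(ids == reference)]]
  recs_by_id <- stats::setNames(records, ids)
  introns$ref_pos <- NA_integer_
  introns$indirect <- FALSE
  for (g in unique(introns$host_gene)) {
    idx <- which(introns$host_gene == g)
    codon_aware <- introns$host_category[idx[1]] == "core_pcg"
    ref_cds <- tryCatch(extract_cds(ref_rec, g, translate = FALSE),
                        error = function(e) NULL)
    for (sp in unique(introns$species_id[idx])) {
      rows <- idx[introns$species_id[idx] == sp]
      if (sp == reference && !is.null(ref_cds)) {
        introns$ref_pos[rows] <- introns$local_pos[rows]
        next
      }
      q_cds <- extract_cds(recs_by_id[[sp]], g, translate = FALSE)
      target <- ref_cds
      indirect <- FALSE
      if (is.null(target)) {
        # host gene absent in the reference: map via the first other
        # species carrying the gene and flag the positions as indirect
        others <- setdiff(unique(introns$species_id[idx]), sp)
        target <- NULL
        for (o in others) {
          target <- tryCatch(extract_cds(recs_by_id[[o]], g, translate = FALSE),
                             error = function(e) NULL)
          if (!is.null(target)) break
        }
        indirect <- TRUE
        if (is.null(target)) target <- q_cds
      }
      introns$ref_pos[rows] <- vapply(
        introns$local_pos[rows],
        function(lp) map_to_reference(lp, q_cds, target, codon_aware),
        integer(1))
      introns$indirect[rows] <- indirect
    }
  }
  introns
}

#' Cluster mapped introns into intron position sets (IPSs)
#'
#' Per host gene, reference positions are clustered by single linkage with
#' a maximum gap of `tolerance` nucleotides between adjacent member
#' positions (so positions \{100, 102, 103\} form one IPS at tolerance 3,
#' \{100, 104\} form two, and a chain \{100, 103, 106\} stays one set).
#' The representative position is the reference species' own position when
#' it is a member, otherwise the minimum member position.
#'
#' @param introns mapped intron tibble (see [map_introns_to_reference()])
#' @param tolerance maximum position difference treated as the same site
#' @param reference reference species id (for representative positions)
#' @return list of class `ips_catalog`: `ips` (one row per IPS), `members`
#'   (introns with `ips_id`), `presence` (IPS x species 0/1 tibble),
#'   `per_species` totals, plus `tolerance` and `reference`
#' @export
cluster_ips <- function(introns, tolerance = 3, reference = NULL) {
  stopifnot("ref_pos" %in% names(introns))
  members <- introns[order(introns$host_gene, introns$ref_pos,
                           introns$species_id), ]
  members$ips_id <- NA_character_
  ips_rows <- list()
  for (g in unique(members$host_gene)) {
    idx <- which(members$host_gene == g)
    pos <- members$ref_pos[idx]
    brk <- cumsum(c(1L, as.integer(diff(pos) > tolerance)))
    for (cl in unique(brk)) {
      sel <- idx[brk == cl]
      p <- members$ref_pos[sel]
      sp <- members$species_id[sel]
      rep_pos <- if (!is.null(reference) && any(sp == reference)) {
        min(p[sp == reference])
      } else min(p)
      id <- paste0(g, "-", rep_pos)
      members$ips_id[sel] <- id
      ips_rows[[length(ips_rows) + 1]] <- tibble::tibble(
        ips_id = id, gene = g, ref_pos = rep_pos,
        n_introns = length(sel), n_species = length(unique(sp)),
        shared = length(unique(sp)) >= 2
      )
    }
  }
  ips <- dplyr::bind_rows(ips_rows)
  if (nrow(ips) == 0) {
    ips <- tibble::tibble(ips_id = character(0), gene = character(0),
                          ref_pos = integer(0), n_introns = integer(0),
                          n_species = integer(0), shared = logical(0))
  }
  # representatives are strictly increasing within a gene, so ids are unique
  stopifnot(!anyDuplicated(ips$ips_id))
  species <- sort(unique(members$species_id))
  presence <- purrr::map_dfr(seq_len(nrow(ips)), function(i) {
    sp <- members$species_id[members$ips_id == ips$ips_id[i]]
    row <- as.list(as.integer(species %in% sp))
    names(row) <- species
    c(list(ips_id = ips$ips_id[i]), row)
  })
  per_species <- members |>
    dplyr::count(.data$species_id, name = "n_introns")
  structure(list(ips = ips, members = members, presence = presence,
                 per_species = per_species, tolerance = tolerance,
                 reference = reference),
            class = "ips_catalog")
}

#' @export
print.ips_catalog <- function(x, ...) {
  cat(sprintf("<ips_catalog> %d IPSs from %d introns across %d species (tolerance %d nt)\n",
              nrow(x$ips), nrow(x$members),
              length(unique(x$members$species_id)), x$tolerance))
  cat(sprintf("  shared (>= 2 species): %d; species-specific: %d\n",
              sum(x$ips$shared), sum(!x$ips$shared)))
  invisible(x)
}

#' Classify an IPS catalog: sharing, per-gene counts, length and phase
#' distributions
#'
#' @param catalog an `ips_catalog` (see [cluster_ips()])
#' @param length_bin width of the intron length histogram bins (nt)
#' @return list of tibbles: `sharing` (IPS counts by number of carrier
#'   species), `per_gene` intron counts, `length_hist`, `phase_hist`
#'   (per species; PCG-hosted introns only)
#' @export
classify_ips <- function(catalog, length_bin = 500) {
  stopifnot(inherits(catalog, "ips_catalog"))
  m <- catalog$members
  sharing <- catalog$ips |>
    dplyr::count(.data$n_species, name = "n_ips") |>
    dplyr::arrange(.data$n_species)
  per_gene <- m |> dplyr::count(.data$host_gene, name = "n_introns")
  length_hist <- m |>
    dplyr::mutate(bin_lo = (.data$length %/% length_bin) * length_bin) |>
    dplyr::count(.data$species_id, .data$bin_lo, name = "n_introns") |>
    dplyr::arrange(.data$species_id, .data$bin_lo)
  phase_hist <- m |>
    dplyr::filter(!is.na(.data$phase)) |>
    dplyr::count(.data$species_id, .data$phase, name = "n_introns")
  list(sharing = sharing, per_gene = per_gene,
       length_hist = length_hist, phase_hist = phase_hist,
       n_shared = sum(catalog$ips$shared),
       n_specific = sum(!catalog$ips$shared))
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Flanking-sequence profile around intron insertion sites
#'
#' Builds a per-position base frequency matrix over the exonic windows
#' up- and downstream of the insertion points (positions -window..-1 and
#' +1..+window), a majority consensus (ties become IUPAC codes), and the
#' tally of the introns' own 5' dinucleotides (group-I-like introns
#' typically start GT).
#'
#' @param introns intron tibble with `flank_up`, `flank_down`, `first_dint`
#' @param window flank width to profile (<= the extracted flank width)
#' @return list: `freq` (long tibble `position`, `base`, `freq`, `n`),
#'   `consensus` string of length `2*window`, `dinucleotide` tally tibble
#' @export
flank_profile <- function(introns, window = 15) {
  stopifnot(nrow(introns) >= 1)
  pad <- function(s, left) {
    s <- toupper(s)
    if (nchar(s) >= window) {
      if (left) substr(s, nchar(s) - window + 1, nchar(s))
      else substr(s, 1, window)
    } else {
      ns <- strrep("N", window - nchar(s))
      if (left) paste0(ns, s) else paste0(s, ns)
    }
  }
  up <- t(vapply(introns$flank_up, function(s) seq_chars(pad(s, TRUE)),
                 character(window)))
  down <- t(vapply(introns$flank_down, function(s) seq_chars(pad(s, FALSE)),
                   character(window)))
  mat <- cbind(up, down)
  positions <- c(-window:-1, 1:window)
  rows <- list()
  consensus <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% .BASES]  # padded/truncated positions excluded
    n <- length(col)
    cnt <- table(factor(col, levels = .BASES))
    freq <- if (n > 0) as.numeric(cnt) / n else rep(NA_real_, 4)
    rows[[j]] <- tibble::tibble(position = positions[j], base = .BASES,
                                freq = freq, n = n)
    if (n == 0) {
      consensus[j] <- "N"
    } else {
      top <- .BASES[cnt == max(cnt)]
      consensus[j] <- .IUPAC[[paste(sort(top), collapse = "")]]
    }
  }
  dint <- introns |>
    dplyr::count(.data$first_dint, name = "n") |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(freq = dplyr::bind_rows(rows),
       consensus = paste(consensus, collapse = ""),
       dinucleotide = dint)
}
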