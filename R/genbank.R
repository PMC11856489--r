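# GenBank flat-file IO. Coordinates are converted between GenBank 1-based
# inclusive (file) and 0-based half-open (in memory) here and only here.

#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses LOCUS/ORGANISM/FEATURES/ORIGIN blocks of one or more records.
#' CDS, tRNA, rRNA and intron features are mapped to typed features with
#' normalized gene names (see [normalize_gene_name()]); CDS whose label and
#' product match no known mitochondrial gene become `un_orf` (or `heg` when
#' the product mentions a homing endonuclease). Introns are taken from
#' explicit `intron` features when present, otherwise inferred from the gaps
#' between `join()` segments of a CDS; when both exist for one gene they are
#' checked for agreement. Records containing an origin-wrapping feature are
#' rotated so that no feature wraps (the offset is recorded in the
#' `rotation_offset` attribute).
#'
#' @param path GenBank flat file (possibly multi-record)
#' @param strict when `TRUE`, malformed feature locations and non-ACGTN
#'   ambiguity codes are errors; when `FALSE` (default) bad features are
#'   skipped with a warning and ambiguity codes are mapped to `N`
#' @return list of [mitogenome()] records
#' @export
read_genbank <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  breaks <- c(0L, which(trimws(lines) == "//"))
  recs <- list()
  for (i in seq_len(length(breaks) - 1)) {
    chunk <- lines[(breaks[i] + 1):(breaks[i + 1] - 1)]
    if (all(trimws(chunk) == "")) next
    recs[[length(recs) + 1]] <- parse_genbank_record(chunk, strict)
  }
  if (length(breaks) == 1 && length(lines) > 0) {
    recs[[1]] <- parse_genbank_record(lines, strict)
  }
  recs
}

#' @noRd
parse_genbank_record <- function(lines, strict) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("no LOCUS line in record")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  organism <- if (length(org_line) > 0) {
    trimws(sub("^\\s+ORGANISM\\s+", "", org_line[1]))
  } else id

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0) stop("record ", id, ": no ORIGIN section")
  seq_lines <- lines[(origin_at[1] + 1):length(lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) stop("record ", id, ": empty sequence")
  if (grepl("[^ACGTN]", sequence)) {
    if (strict) stop("record ", id, ": ambiguity codes other than N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  n <- nchar(sequence)

  feat_at <- grep("^FEATURES", lines)
  raw_feats <- if (length(feat_at) > 0) {
    parse_feature_table(lines[(feat_at[1] + 1):(origin_at[1] - 1)], id, strict)
  } else list()

  built <- build_features(raw_feats, n, id, strict)
  rec <- mitogenome(id, sequence, built$features, organism, topology)
  if (built$rotate > 0) rec <- rotate_genome(rec, built$rotate)
  # join-gap introns are inferred only after any rotation, so that
  # wrap-split segments cannot masquerade as gaps
  rot <- attr(rec, "rotation_offset")
  rec <- mitogenome(rec$id, rec$sequence, infer_join_introns(rec$features),
                    rec$organism, rec$topology)
  if (!is.null(rot)) attr(rec, "rotation_offset") <- rot
  rec
}

# Split the FEATURES block into (key, location, qualifiers) entries.
#' @noRd
parse_feature_table <- function(lines, id, strict) {
  is_key <- grepl("^ {5}\\S", lines)
  idx <- which(is_key)
  out <- list()
  for (j in seq_along(idx)) {
    from <- idx[j]
    to <- if (j < length(idx)) idx[j + 1] - 1 else length(lines)
    block <- lines[from:to]
    key <- sub("^ {5}(\\S+).*", "\\1", block[1])
    rest <- trimws(substring(block, 22))
    # location may continue until the first qualifier line
    qual_start <- grep("^/", rest)
    loc_end <- if (length(qual_start) > 0) qual_start[1] - 1 else length(rest)
    location <- paste(rest[1:loc_end], collapse = "")
    quals <- character(0)
    if (length(qual_start) > 0) {
      qlines <- rest[qual_start[1]:length(rest)]
      starts <- grepl("^/", qlines)
      grp <- cumsum(starts)
      quals <- vapply(split(qlines, grp), paste, character(1), collapse = " ")
    }
    out[[j]] <- list(key = key, location = location, qualifiers = quals, id = id)
  }
  out
}

#' @noRd
get_qualifier <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- grep(pat, quals, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  unname(gsub('^"|"$', "", sub(pat, "", hit[1])))
}

# Parse a GenBank location string into 1-based inclusive segments.
# Returns list(segments = data.frame(start, end), strand).
#' @noRd
parse_location <- function(loc) {
  loc <- gsub("[<>\\s]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  if (grepl("[()]", loc)) stop("unsupported location: ", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0) stop("empty location")
  seg <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)(\\.\\.(\\d+))?$", p))[[1]]
    if (length(m) == 0) stop("malformed location part: ", p)
    a <- as.integer(m[2])
    b <- if (m[4] == "" || is.na(m[4])) a else as.integer(m[4])
    c(a, b)
  })
  seg <- do.call(rbind, seg)
  list(segments = data.frame(start = seg[, 1], end = seg[, 2]),
       strand = strand)
}

.HEG_PATTERN <- "(?i)laglidadg|giy.?yig|homing.endonuclease"

# Turn raw feature entries into the typed feature tibble; detect wraps.
#' @noRd
build_features <- function(raw, genome_len, id, strict) {
  rows <- list()
  rotate <- 0L
  for (f in raw) {
    if (!f$key %in% c("CDS", "tRNA", "rRNA", "intron")) next
    loc <- tryCatch(parse_location(f$location), error = function(e) e)
    if (inherits(loc, "error")) {
      if (strict) stop("record ", id, ": ", conditionMessage(loc))
      warning("record ", id, ": skipping feature with ", conditionMessage(loc))
      next
    }
    seg <- loc$segments
    # origin wrap: a single span with start > end, or a join whose
    # segments step backwards past the origin
    wrap <- any(seg$start > seg$end) ||
      (nrow(seg) > 1 && any(diff(seg$start) < 0))
    if (wrap) rotate <- max(rotate, seg$start[1] - 1L)

    gene_raw <- get_qualifier(f$qualifiers, "gene")
    if (is.na(gene_raw)) gene_raw <- get_qualifier(f$qualifiers, "locus_tag")
    product <- get_qualifier(f$qualifiers, "product")
    note <- get_qualifier(f$qualifiers, "note")
    label <- if (!is.na(gene_raw)) gene_raw else if (!is.na(product)) product else note
    canon <- normalize_gene_name(label)
    if (is.na(canon) && !is.na(product)) canon <- normalize_gene_name(product)

    cat_gene <- classify_feature(f$key, canon, label, product, note)
    if (is.null(cat_gene)) next
    # 1-based inclusive -> 0-based half-open; wrap segments split
    segs <- list()
    for (k in seq_len(nrow(seg))) {
      a <- seg$start[k]; b <- seg$end[k]
      if (a <= b) {
        segs[[length(segs) + 1]] <- c(a - 1L, b)
      } else {
        segs[[length(segs) + 1]] <- c(a - 1L, genome_len)
        segs[[length(segs) + 1]] <- c(0L, b)
      }
    }
    segs <- do.call(rbind, segs)
    seg_tbl <- tibble::tibble(start = as.integer(segs[, 1]),
                              end = as.integer(segs[, 2]))
    if (loc$strand == "-") seg_tbl <- seg_tbl[order(-seg_tbl$start), ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      category = cat_gene$category, gene_name = cat_gene$gene_name,
      strand = loc$strand,
      parent = cat_gene$parent %||% NA_character_,
      segments = list(seg_tbl)
    )
  }
  feats <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty_features()
  list(features = feats, rotate = rotate)
}

#' @noRd
classify_feature <- function(key, canon, label, product, note) {
  txt <- paste(stats::na.omit(c(label, product, note)), collapse = " ")
  if (key == "CDS") {
    if (!is.na(canon) && canon %in% .CORE_PCGS) {
      return(list(category = "core_pcg", gene_name = canon, parent = NULL))
    }
    if (grepl(.HEG_PATTERN, txt, perl = TRUE)) {
      host <- if (!is.na(note)) normalize_gene_name(sub(".*intron of ", "", note)) else NA
      return(list(category = "heg",
                  gene_name = if (!is.na(label)) label else "heg",
                  parent = if (!is.na(host)) host else NULL))
    }
    return(list(category = "un_orf",
                gene_name = if (!is.na(label)) label else "orf", parent = NULL))
  }
  if (key == "tRNA") {
    nm <- if (!is.na(label)) gsub("[^A-Za-z0-9()\\-]", "", label) else "trn"
    return(list(category = "trna", gene_name = nm, parent = NULL))
  }
  if (key == "rRNA") {
    if (is.na(canon) || !canon %in% .RRNAS) return(NULL)
    return(list(category = "rrna", gene_name = canon, parent = NULL))
  }
  if (key == "intron") {
    parent <- if (!is.na(label)) normalize_gene_name(label) else NA_character_
    nm <- if (!is.na(note)) note else paste0(parent %||% "intron", "-intron")
    return(list(category = "intron", gene_name = nm, parent = parent))
  }
  NULL
}

# Infer intron features from gaps between join() segments, unless explicit
# intron features for the same host gene already cover them.
#' @noRd
infer_join_introns <- function(feats) {
  if (nrow(feats) == 0) return(feats)
  hosts <- feats[feats$category %in% c("core_pcg", "rrna"), ]
  new_rows <- list()
  for (i in seq_len(nrow(hosts))) {
    seg <- hosts$segments[[i]]
    if (nrow(seg) < 2) next
    g <- dplyr::arrange(seg, .data$start)
    gaps <- tibble::tibble(start = g$end[-nrow(g)], end = g$start[-1])
    gaps <- gaps[gaps$end > gaps$start, ]
    if (nrow(gaps) == 0) next
    have <- feats[feats$category == "intron" &
                    !is.na(feats$parent) &
                    feats$parent == hosts$gene_name[i], ]
    for (k in seq_len(nrow(gaps))) {
      covered <- FALSE
      for (j in seq_len(nrow(have))) {
        hseg <- have$segments[[j]]
        if (any(hseg$start == gaps$start[k] & hseg$end == gaps$end[k])) {
          covered <- TRUE
          break
        }
        if (any(pmax(hseg$start, gaps$start[k]) < pmin(hseg$end, gaps$end[k]))) {
          warning("intron feature and join() gap disagree for gene ",
                  hosts$gene_name[i])
          covered <- TRUE
          break
        }
      }
      if (covered) next
      new_rows[[length(new_rows) + 1]] <- tibble::tibble(
        category = "intron",
        gene_name = paste0(hosts$gene_name[i], "-i", k),
        strand = hosts$strand[i],
        parent = hosts$gene_name[i],
        segments = list(tibble::tibble(start = gaps$start[k],
                                       end = gaps$end[k]))
      )
    }
  }
  if (length(new_rows) > 0) feats <- dplyr::bind_rows(feats, new_rows)
  feats
}

#' Write mitogenome records as a GenBank flat file
#'
#' The writer emits CDS (with `join()` for multi-exon genes), tRNA, rRNA and
#' intron features in a form [read_genbank()] maps back to the identical
#' typed feature list (round-trip property).
#'
#' @param records a [mitogenome()] or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genbank <- function(records, path) {
  if (is_mitogenome(records)) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(format_genbank_record(rec), con)
  }
  invisible(path)
}

#' @noRd
format_genbank_record <- function(rec) {
  out <- character(0)
  out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %s   PLN",
                        rec$id, rec$length, rec$topology))
  out <- c(out, sprintf("DEFINITION  %s mitochondrion, complete genome.",
                        rec$organism))
  out <- c(out, "SOURCE      mitochondrion")
  out <- c(out, sprintf("  ORGANISM  %s", rec$organism))
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     source          1..%d", rec$length))

  feats <- rec$features
  for (i in seq_len(nrow(feats))) {
    cat_i <- feats$category[i]
    key <- switch(cat_i, core_pcg = "CDS", un_orf = "CDS", heg = "CDS",
                  trna = "tRNA", rrna = "rRNA", intron = "intron")
    seg <- dplyr::arrange(feats$segments[[i]], .data$start)
    locs <- sprintf("%d..%d", seg$start + 1L, seg$end)
    loc <- if (length(locs) > 1) {
      paste0("join(", paste(locs, collapse = ","), ")")
    } else locs
    if (feats$strand[i] == "-") loc <- paste0("complement(", loc, ")")
    out <- c(out, sprintf("     %-15s %s", key, loc))
    qual <- switch(
      cat_i,
      core_pcg = sprintf('/gene="%s"', feats$gene_name[i]),
      un_orf = sprintf('/gene="%s"', feats$gene_name[i]),
      heg = c(sprintf('/gene="%s"', feats$gene_name[i]),
              '/product="LAGLIDADG homing endonuclease"',
              if (!is.na(feats$parent[i]))
                sprintf('/note="intron of %s"', feats$parent[i])),
      trna = sprintf('/gene="%s"', feats$gene_name[i]),
      rrna = sprintf('/gene="%s"', feats$gene_name[i]),
      intron = c(sprintf('/gene="%s"', feats$parent[i]),
                 sprintf('/note="%s"', feats$gene_name[i]))
    )
    qual <- qual[!is.na(qual)]
    out <- c(out, sprintf("                     %s", qual))
    if (cat_i %in% c("core_pcg", "un_orf", "heg")) {
      out <- c(out, "                     /transl_table=4")
    }
  }

  out <- c(out, "ORIGIN")
  s <- tolower(rec$sequence)
  starts <- seq(1, nchar(s), by = 60)
  for (st in starts) {
    blockpos <- seq(st, min(st + 59, nchar(s)), by = 10)
    blocks <- substring(s, blockpos, pmin(blockpos + 9, nchar(s)))
    out <- c(out, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  c(out, "//")
}

#' Read sequences from a FASTA file as bare (feature-less) records
#' @param path FASTA file
#' @return list of [mitogenome()] records with empty feature tables
#' @export
read_fasta_genomes <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  purrr::map2(as.character(ss), names(ss), function(s, nm) {
    id <- strsplit(nm, "\\s+")[[1]][1]
    mitogenome(id, gsub("[^ACGTN]", "N", toupper(s)), organism = nm)
  })
}

#' Write record sequences to FASTA
#' @param records list of [mitogenome()] records
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta_genomes <- function(records, path) {
  if (is_mitogenome(records)) records <- list(records)
  ss <- Biostrings::DNAStringSet(
    stats::setNames(purrr::map_chr(records, "sequence"),
                    purrr::map_chr(records, "id")))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
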