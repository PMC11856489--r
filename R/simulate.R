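# Mitogenome evolution simulator. Generates an ancestral annotated genome
# (core genes + rRNAs in the conserved Hypocreales order, tRNAs, un_ORFs,
# AT-rich intergenic spacers), evolves it along a phylogeny under a
# Kimura-2-parameter substitution process (with purifying selection on
# coding genes approximated by rejection of nonsynonymous changes), gains
# and loses group-I-like introns, and emits annotated records together
# with the full ground truth.

#' Simulation configuration
#'
#' Defaults emulate a small clade of congeneric fungal mitogenomes:
#' circular genomes around 40-100 kb, GC about 27% with positive AT and GC
#' skews, 15 core PCGs + rnl + rns in the shared Hypocreales order, 26
#' tRNAs, 1-2 kb introns (log-normal, median ~1.4 kb) frequently carrying
#' homing-endonuclease ORFs, and free-standing un_ORFs.
#'
#' @param seed RNG seed (identical config => byte-identical output)
#' @param tree newick string with branch lengths in substitutions/site
#' @param kappa transition/transversion rate ratio of the K2P process
#' @param omega target Ka/Ks for protein-coding genes (acceptance
#'   probability of nonsynonymous changes)
#' @param intron_gain_rate,intron_loss_rate events per host gene per unit
#'   branch length
#' @param ancestral_introns introns present in the root genome
#' @param intron_meanlog,intron_sdlog log-normal intron length parameters
#'   (median exp(meanlog) ~ 1.4 kb, enriched in the 1-2 kb bin)
#' @param heg_prob probability an intron carries a homing-endonuclease ORF
#' @param phase0_prob probability a new intron insertion is snapped to a
#'   codon boundary (phase 0), reflecting the phase-0 excess typical of
#'   group-I intron insertion sites; the remainder falls uniformly
#' @param n_trna number of tRNA genes (25-27 in the emulated genomes)
#' @param intergenic_mean mean spacer length (nt)
#' @param un_orf_count,un_orf_len free-standing ORFs of unknown function
#' @param base_freqs root base frequencies (AT-rich, both skews positive)
#' @param indel_rate codon-multiple indel events per gene per unit branch
#'   length (0 = off; insertions/deletions exercise alignment-mediated
#'   intron position mapping)
#' @param noncoding_indel_rate small (1-12 nt) indel events per
#'   tRNA/spacer/un_ORF element per unit branch length, giving the
#'   non-coding fractions the length variation real cohorts show
#' @param order_overrides named list: species id -> marker vector, for
#'   planting gene-order rearrangements
#' @return list of class `sim_config`
#' @export
simulation_config <- function(
    seed = 1729,
    tree = "(((A_ref:0.02,B:0.02):0.02,(C:0.03,D:0.03):0.02):0.02,(E:0.04,F:0.04):0.02,G:0.07);",
    kappa = 2, omega = 0.2,
    intron_gain_rate = 6, intron_loss_rate = 1,
    ancestral_introns = 12,
    intron_meanlog = log(1400), intron_sdlog = 0.35,
    heg_prob = 0.7, phase0_prob = 0.5,
    n_trna = 26, intergenic_mean = 150,
    un_orf_count = 8, un_orf_len = 600,
    base_freqs = c(A = 0.38, C = 0.12, G = 0.15, T = 0.35),
    indel_rate = 0,
    noncoding_indel_rate = 2,
    order_overrides = list()) {
  stopifnot(intron_gain_rate >= 0, intron_loss_rate >= 0, kappa > 0,
            omega >= 0, omega <= 1, n_trna >= 1,
            abs(sum(base_freqs) - 1) < 1e-8)
  if (intron_loss_rate > 0 && intron_gain_rate == 0 && ancestral_introns == 0) {
    warning("loss rate set with no intron gains and no ancestral introns")
  }
  structure(as.list(environment()), class = "sim_config")
}

# realistic spliced lengths (nt, multiples of 3 for PCGs)
.SIM_GENE_LEN <- c(
  atp6 = 774, atp8 = 147, atp9 = 222, cob = 1164, cox1 = 1596, cox2 = 750,
  cox3 = 810, nad1 = 1086, nad2 = 1665, nad3 = 417, nad4 = 1479,
  nad4L = 270, nad5 = 1980, nad6 = 630, rps3 = 1110, rnl = 3200, rns = 1500)

#' @noRd
sample_bases <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# random in-frame coding sequence with no internal stop, ATG start,
# TAA/TAG stop
#' @noRd
random_coding <- function(len, freqs) {
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- len / 3 - 2
  pool <- .CODONS[.GC4 != "*"]
  w <- vapply(strsplit(pool, ""), function(ch) prod(freqs[ch]), numeric(1))
  body <- sample(pool, ncod, replace = TRUE, prob = w)
  c("ATG", body, sample(c("TAA", "TAG"), 1)) |>
    paste(collapse = "") |>
    seq_chars()
}

# evolve a character vector under K2P(kappa); when omega < 1 the vector is
# treated as in-frame coding and nonsynonymous changes are accepted with
# probability omega (changes creating stops are rejected). Returns the
# vector plus the realized substitution count.
#' @noRd
evolve_chars <- function(chv, t, kappa, omega = 1) {
  L <- length(chv)
  n_events <- stats::rpois(1, t * L)
  subs <- 0L
  if (n_events == 0) return(list(seq = chv, subs = 0L))
  sites <- sample.int(L, n_events, replace = TRUE)
  p_ti <- kappa / (kappa + 2)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_set <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  for (s in sites) {
    cur <- chv[s]
    if (!cur %in% .BASES) next
    new <- if (stats::runif(1) < p_ti) ti_partner[[cur]] else
      sample(tv_set[[cur]], 1)
    if (omega < 1) {
      ci <- (s - 1) %/% 3
      cod_idx <- (ci * 3 + 1):(ci * 3 + 3)
      old_codon <- paste(chv[cod_idx], collapse = "")
      tmp <- chv[cod_idx]
      tmp[s - ci * 3] <- new
      new_codon <- paste(tmp, collapse = "")
      if (ci == 0 || max(cod_idx) == L) next        # freeze start/stop codon
      if (is.na(.GC4[new_codon]) || .GC4[new_codon] == "*") next
      if (.GC4[new_codon] != .GC4[old_codon] &&
            stats::runif(1) >= omega) next
    }
    chv[s] <- new
    subs <- subs + 1L
  }
  list(seq = chv, subs = subs)
}

#' Evolve a nucleotide sequence under the simulator's K2P process
#'
#' Exported primitive used for estimator-recovery experiments: with
#' `omega = 1` every event substitutes, so the expected K2P distance
#' equals `t`; with `omega < 1` the sequence is treated as in-frame coding
#' under purifying selection.
#'
#' @param seq nucleotide string
#' @param t branch length (substitution events per site)
#' @param kappa transition/transversion rate ratio
#' @param omega acceptance probability of nonsynonymous changes
#' @return evolved nucleotide string
#' @export
sim_evolve <- function(seq, t, kappa = 2, omega = 1) {
  paste(evolve_chars(seq_chars(seq), t, kappa, omega)$seq, collapse = "")
}

#' @noRd
new_intron <- function(cfg, env) {
  len <- round(stats::rlnorm(1, cfg$intron_meanlog, cfg$intron_sdlog))
  len <- max(len, 120L)
  ch <- sample_bases(len, cfg$base_freqs)
  ch[1] <- "G"; ch[2] <- "T"; ch[len] <- "G"
  heg_start <- NA_integer_; heg_len <- 0L
  if (stats::runif(1) < cfg$heg_prob && len >= 800) {
    heg_len <- 3L * (100 + sample.int(60, 1))       # 300-480 aa ORF region
    heg_len <- min(heg_len, 3L * ((len - 80) %/% 3))
    orf <- random_coding(heg_len, cfg$base_freqs)
    heg_start <- sample.int(len - heg_len - 40L, 1) + 20L
    ch[heg_start:(heg_start + heg_len - 1L)] <- orf
  }
  env$counter <- env$counter + 1L
  list(seq = ch, len = len, heg_start = heg_start, heg_len = heg_len,
       uid = env$counter)
}

#' @noRd
gain_intron <- function(state, cfg, env, branch, truth) {
  hosts <- names(state$genes)
  w <- vapply(state$genes, function(g) length(g$coding), numeric(1))
  g <- sample(hosts, 1, prob = w)
  gene <- state$genes[[g]]
  L <- length(gene$coding)
  taken <- gene$introns$offset
  draw <- function() {
    off <- sample(3:(L - 3), 1)
    if (gene$category == "core_pcg" && stats::runif(1) < cfg$phase0_prob) {
      off <- min(max(3L * round(off / 3), 3L), 3L * ((L - 3L) %/% 3L))
    }
    off
  }
  off <- draw()
  tries <- 0
  while (off %in% taken && tries < 50) {
    off <- draw(); tries <- tries + 1
  }
  intr <- new_intron(cfg, env)
  gene$introns <- dplyr::bind_rows(gene$introns, tibble::tibble(
    key = paste0(g, "-", off), uid = intr$uid, offset = off,
    length = intr$len, heg_start = intr$heg_start, heg_len = intr$heg_len,
    seq = list(intr$seq)))
  state$genes[[g]] <- gene
  truth$events <- dplyr::bind_rows(truth$events, tibble::tibble(
    branch = branch, type = "gain", gene = g, offset = off,
    phase = if (state$genes[[g]]$category == "core_pcg") off %% 3 else NA_integer_,
    length = intr$len))
  list(state = state, truth = truth)
}

#' Simulate an annotated mitogenome cohort with known truth
#'
#' @param cfg a [simulation_config()]
#' @return list of class `sim_result`: `records` (annotated
#'   [mitogenome()] objects, one per tree leaf), `truth` (list: `tree`
#'   phylo, `events` intron event log, `introns` per-leaf intron table,
#'   `ips_matrix` site x species presence tibble keyed by ancestral
#'   (gene, offset), `components` per-leaf component lengths, `branch_subs`
#'   realized substitutions per branch), and `config`
#' @export
simulate_mitogenomes <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- ape::read.tree(text = cfg$tree)
  stopifnot(!is.null(tree), length(tree$tip.label) >= 2)

  env <- new.env(parent = emptyenv()); env$counter <- 0L
  order0 <- hypocreales_order()$marker
  truth <- list(events = tibble::tibble(branch = character(0),
                                        type = character(0),
                                        gene = character(0),
                                        offset = integer(0),
                                        phase = integer(0),
                                        length = integer(0)),
                branch_subs = tibble::tibble(branch = character(0),
                                             subs = integer(0)))

  # --- ancestral genome -----------------------------------------------------
  genes <- list()
  for (g in order0) {
    len <- .SIM_GENE_LEN[[g]]
    is_pcg <- g %in% .CORE_PCGS
    coding <- if (is_pcg) random_coding(len, cfg$base_freqs) else
      sample_bases(len, cfg$base_freqs)
    genes[[g]] <- list(name = g,
                       category = if (is_pcg) "core_pcg" else "rrna",
                       coding = coding,
                       introns = tibble::tibble(
                         key = character(0), uid = integer(0),
                         offset = integer(0), length = integer(0),
                         heg_start = integer(0), heg_len = integer(0),
                         seq = list()))
  }
  # tRNAs and un_ORFs distributed round-robin over the 17 intergenic gaps
  gaps <- rep(list(list()), length(order0))
  slot <- 1
  add_item <- function(item) {
    gaps[[slot]][[length(gaps[[slot]]) + 1]] <<- item
    slot <<- if (slot == length(gaps)) 1 else slot + 1
  }
  for (i in seq_len(cfg$n_trna)) {
    add_item(list(type = "trna", name = paste0("trn", i),
                  seq = sample_bases(72, cfg$base_freqs)))
  }
  for (i in seq_len(cfg$un_orf_count)) {
    add_item(list(type = "un_orf", name = paste0("orf", i),
                  seq = random_coding(cfg$un_orf_len, cfg$base_freqs)))
  }
  # spacers: one before every element realized; store per gap as lead spacer
  spacer <- function() {
    n <- max(30L, stats::rpois(1, cfg$intergenic_mean))
    sample_bases(n, cfg$base_freqs)
  }
  for (k in seq_along(gaps)) {
    gaps[[k]] <- c(list(list(type = "spacer", name = NA, seq = spacer())),
                   gaps[[k]])
    # spacers between items
    if (length(gaps[[k]]) > 1) {
      expanded <- list(gaps[[k]][[1]])
      for (it in gaps[[k]][-1]) {
        expanded[[length(expanded) + 1]] <- it
        expanded[[length(expanded) + 1]] <-
          list(type = "spacer", name = NA, seq = spacer())
      }
      gaps[[k]] <- expanded
    }
  }
  state0 <- list(genes = genes, gaps = gaps)
  for (i in seq_len(cfg$ancestral_introns)) {
    res <- gain_intron(state0, cfg, env, branch = "root", truth)
    state0 <- res$state; truth <- res$truth
  }

  # --- evolve along the tree ------------------------------------------------
  n_tips <- length(tree$tip.label)
  root <- n_tips + 1L
  node_label <- function(v) {
    if (v <= n_tips) tree$tip.label[v] else paste0("node", v)
  }
  leaves <- list()
  evolve_branch <- function(state, t, branch) {
    subs <- 0L
    for (g in names(state$genes)) {
      gene <- state$genes[[g]]
      om <- if (gene$category == "core_pcg") cfg$omega else 1
      ev <- evolve_chars(gene$coding, t, cfg$kappa, om)
      gene$coding <- ev$seq; subs <- subs + ev$subs
      if (nrow(gene$introns) > 0) {
        keep <- stats::runif(nrow(gene$introns)) >=
          1 - exp(-cfg$intron_loss_rate * t)
        for (r in which(!keep)) {
          off_r <- gene$introns$offset[r]
          len_r <- gene$introns$length[r]
          truth$events <<- dplyr::bind_rows(truth$events, tibble::tibble(
            branch = branch, type = "loss", gene = g,
            offset = off_r, phase = NA_integer_, length = len_r))
        }
        gene$introns <- gene$introns[keep, ]
        gene$introns$seq <- purrr::map(gene$introns$seq, function(s) {
          evolve_chars(s, t, cfg$kappa, 1)$seq
        })
      }
      if (cfg$indel_rate > 0 && gene$category == "core_pcg") {
        gene <- apply_indels(gene, t, cfg)
      }
      state$genes[[g]] <- gene
    }
    state$gaps <- purrr::map(state$gaps, function(gap) {
      purrr::map(gap, function(it) {
        it$seq <- evolve_chars(it$seq, t, cfg$kappa, 1)$seq
        if (cfg$noncoding_indel_rate > 0) {
          it$seq <- noncoding_indels(it$seq, it$type, t,
                                     cfg$noncoding_indel_rate, cfg)
        }
        it
      })
    })
    n_gain <- stats::rpois(1, cfg$intron_gain_rate * t * length(state$genes))
    for (i in seq_len(n_gain)) {
      res <- gain_intron(state, cfg, env, branch, truth)
      state <- res$state; truth <<- res$truth
    }
    truth$branch_subs <<- dplyr::bind_rows(
      truth$branch_subs, tibble::tibble(branch = branch, subs = subs))
    state
  }
  recurse <- function(node, state) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (k in kids) {
      t <- tree$edge.length[tree$edge[, 1] == node & tree$edge[, 2] == k]
      st <- evolve_branch(state, t, node_label(k))
      if (k <= n_tips) {
        leaves[[tree$tip.label[k]]] <<- st
      } else {
        recurse(k, st)
      }
    }
  }
  recurse(root, state0)

  # --- realize leaf records and truth tables --------------------------------
  records <- list()
  intron_rows <- list()
  comp_rows <- list()
  for (sp in tree$tip.label) {
    ord <- cfg$order_overrides[[sp]]
    if (is.null(ord)) ord <- order0
    rec <- realize_record(sp, leaves[[sp]], ord)
    records[[sp]] <- rec$record
    intron_rows[[sp]] <- rec$introns
    comp_rows[[sp]] <- rec$components
  }
  introns <- dplyr::bind_rows(intron_rows)
  ips_matrix <- if (nrow(introns) > 0) {
    introns |>
      dplyr::distinct(.data$key, .data$gene, .data$offset, .data$species_id) |>
      dplyr::mutate(present = 1L) |>
      tidyr::pivot_wider(names_from = "species_id", values_from = "present",
                         values_fill = 0L) |>
      dplyr::arrange(.data$gene, .data$offset)
  } else tibble::tibble(key = character(0))
  structure(
    list(records = unname(records),
         truth = list(tree = tree, events = truth$events,
                      introns = introns, ips_matrix = ips_matrix,
                      components = dplyr::bind_rows(comp_rows),
                      branch_subs = truth$branch_subs),
         config = cfg),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d genomes (%s), %d intron sites\n",
              length(x$records),
              paste(range(purrr::map_int(x$records, "length")),
                    collapse = "-"),
              nrow(x$truth$ips_matrix)))
  invisible(x)
}

# small indels for non-coding elements: arbitrary lengths for spacers and
# tRNAs, codon multiples at codon boundaries for un_ORFs (keeps them ORFs)
#' @noRd
noncoding_indels <- function(ch, type, t, rate, cfg) {
  n_events <- stats::rpois(1, rate * t)
  for (i in seq_len(n_events)) {
    L <- length(ch)
    if (type == "un_orf") {
      ncod <- L %/% 3
      if (ncod < 12) break
      len <- 3L * sample.int(3, 1)
      at <- 3L * sample(seq(2, ncod - 4), 1)
      if (stats::runif(1) < 0.5) {
        ins <- random_coding(len + 6L, cfg$base_freqs)[4:(3 + len)]
        ch <- append(ch, ins, after = at)
      } else if (at + len < L - 3) {
        ch <- ch[-((at + 1):(at + len))]
      }
    } else {
      min_len <- if (type == "trna") 60L else 30L
      len <- sample.int(12, 1)
      at <- sample.int(max(L - len - 1L, 1L), 1)
      if (stats::runif(1) < 0.5) {
        ch <- append(ch, sample_bases(len, cfg$base_freqs), after = at)
      } else if (L - len >= min_len) {
        ch <- ch[-((at + 1):(at + len))]
      }
    }
  }
  ch
}

# codon-multiple indels at codon boundaries; intron offsets are shifted
#' @noRd
apply_indels <- function(gene, t, cfg) {
  n <- stats::rpois(1, cfg$indel_rate * t)
  for (i in seq_len(n)) {
    L <- length(gene$coding)
    ncod <- L %/% 3
    if (ncod < 10) break
    len <- 3L * sample.int(3, 1)                     # 3, 6 or 9 nt
    at_codon <- sample(seq(2, ncod - 2), 1)          # boundary after codon
    at <- 3L * at_codon
    if (stats::runif(1) < 0.5) {                     # insertion
      ins <- random_coding(len + 6L, cfg$base_freqs)[4:(3 + len)]
      gene$coding <- append(gene$coding, ins, after = at)
      gene$introns$offset <- ifelse(gene$introns$offset > at,
                                    gene$introns$offset + len,
                                    gene$introns$offset)
    } else {                                         # deletion
      if (at + len >= L - 3) next
      if (any(gene$introns$offset > at & gene$introns$offset <= at + len)) next
      gene$coding <- gene$coding[-((at + 1):(at + len))]
      gene$introns$offset <- ifelse(gene$introns$offset > at + len,
                                    gene$introns$offset - len,
                                    gene$introns$offset)
    }
  }
  gene
}

#' @noRd
realize_record <- function(sp, state, ord) {
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  introns_out <- list()
  comp <- c(core_pcg = 0L, rna_region = 0L, intronic = 0L, un_orf = 0L,
            intergenic = 0L, heg = 0L)
  add_feat <- function(category, gene_name, parent, segs) {
    feats[[length(feats) + 1]] <<- tibble::tibble(
      category = category, gene_name = gene_name, strand = "+",
      parent = parent, segments = list(segs))
  }
  for (k in seq_along(ord)) {
    gene <- state$genes[[ord[k]]]
    itr <- gene$introns[order(gene$introns$offset), ]
    offs <- itr$offset
    bounds <- c(0L, offs, length(gene$coding))
    exon_segs <- list()
    for (e in seq_len(length(bounds) - 1)) {
      exon <- gene$coding[(bounds[e] + 1):bounds[e + 1]]
      exon_segs[[e]] <- c(pos, pos + length(exon))
      pieces <- c(pieces, paste(exon, collapse = ""))
      pos <- pos + length(exon)
      if (e <= nrow(itr)) {
        iseq <- itr$seq[[e]]
        istart <- pos
        pieces <- c(pieces, paste(iseq, collapse = ""))
        pos <- pos + length(iseq)
        add_feat("intron", paste0(gene$name, "-i", e), gene$name,
                 tibble::tibble(start = istart, end = pos))
        comp["intronic"] <- comp["intronic"] + length(iseq)
        if (!is.na(itr$heg_start[e])) {
          hs <- istart + itr$heg_start[e] - 1L
          add_feat("heg", paste0(gene$name, "-i", e, "-heg"), gene$name,
                   tibble::tibble(start = hs, end = hs + itr$heg_len[e]))
          comp["heg"] <- comp["heg"] + itr$heg_len[e]
        }
        ph <- if (gene$category == "core_pcg") itr$offset[e] %% 3 else
          NA_integer_
        introns_out[[length(introns_out) + 1]] <- tibble::tibble(
          species_id = sp, key = itr$key[e], uid = itr$uid[e],
          gene = gene$name, offset = itr$offset[e],
          length = length(iseq), phase = ph,
          has_heg = !is.na(itr$heg_start[e]))
      }
    }
    seg_tbl <- tibble::tibble(
      start = vapply(exon_segs, `[`, integer(1), 1),
      end = vapply(exon_segs, `[`, integer(1), 2))
    add_feat(gene$category, gene$name, NA_character_, seg_tbl)
    comp[if (gene$category == "core_pcg") "core_pcg" else "rna_region"] <-
      comp[[if (gene$category == "core_pcg") "core_pcg" else "rna_region"]] +
      length(gene$coding)
    for (it in state$gaps[[k]]) {
      a <- pos
      pieces <- c(pieces, paste(it$seq, collapse = ""))
      pos <- pos + length(it$seq)
      if (it$type == "trna") {
        add_feat("trna", it$name, NA_character_,
                 tibble::tibble(start = a, end = pos))
        comp["rna_region"] <- comp["rna_region"] + length(it$seq)
      } else if (it$type == "un_orf") {
        add_feat("un_orf", it$name, NA_character_,
                 tibble::tibble(start = a, end = pos))
        comp["un_orf"] <- comp["un_orf"] + length(it$seq)
      } else {
        comp["intergenic"] <- comp["intergenic"] + length(it$seq)
      }
    }
  }
  record <- mitogenome(sp, paste(pieces, collapse = ""),
                       dplyr::bind_rows(feats), organism = sp)
  list(record = record,
       introns = if (length(introns_out) > 0) dplyr::bind_rows(introns_out)
                 else tibble::tibble(species_id = character(0)),
       components = tibble::tibble(species_id = sp,
                                   core_pcg = comp[["core_pcg"]],
                                   rna_region = comp[["rna_region"]],
                                   intronic = comp[["intronic"]],
                                   un_orf = comp[["un_orf"]],
                                   intergenic = comp[["intergenic"]],
                                   heg = comp[["heg"]],
                                   total = record$length))
}
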