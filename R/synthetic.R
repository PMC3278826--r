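# Synthetic benchmark generator.  Emulates the statistical structure of
# carboxylated proteins: Glu-rich flanks around the modified glutamate with
# arginine enrichment at characteristic offsets, Glu depletion at -2/+2,
# elevated solvent accessibility at the site (mean 37.8% at the centre, a
# dip at -2/+2), and coil/helix-dominated secondary structure.

#' Specification of the synthetic dataset generator
#'
#' The defaults mirror the composition and structure signals reported for
#' real carboxylation sites, at a desk scale of 80 proteins with roughly a
#' 1:2 positive:negative glutamate ratio.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (uniform).
#' @param pos_per_protein Carboxylated glutamates planted per protein.
#' @param neg_per_protein Decoy (background-context) glutamates planted per
#'   protein; further negatives arise naturally from glutamates drawn in the
#'   Glu-enriched flanks of positive windows.
#' @param background Named probability vector over the 20 residues used for
#'   inter-site sequence and decoy flanks.  Glutamate is suppressed outside
#'   planted windows so the negative class stays near the target ratio.
#' @param glu_enriched_offsets,glu_enriched Offsets (relative to the site)
#'   with elevated Glu probability, and that probability.
#' @param glu_depleted_offsets,glu_depleted Offsets with depleted Glu.
#' @param arg_enriched_offsets,arg_enriched Offsets with elevated Arg.
#' @param asa_pos_means Named list of positive-window ASA means (percent):
#'   `center`, `near` (offsets -1/+1), `dip` (-2/+2), `flank` (rest).
#' @param asa_bg_mean,asa_sd Background ASA mean and common SD (percent);
#'   draws are clipped to `[0, 100]`.
#' @param ss_pos,ss_bg Secondary-structure state probabilities `(H, E, C)`
#'   inside positive windows and elsewhere.
#' @param signal_n Half-width of the planted signal (7: offsets -7..+7).
#' @param site_margin Minimum distance of a planted site from the termini.
#' @param duplicate_proteins Number of leading proteins to duplicate
#'   verbatim (id suffix `_dup`), for exercising homology reduction.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A `gla_generator_spec` list.
#' @export
gla_generator_spec <- function(n_proteins = 80L,
                               length_range = c(200L, 600L),
                               pos_per_protein = 4L,
                               neg_per_protein = 2L,
                               background = NULL,
                               glu_enriched_offsets = c(-7, -6, -4, -3, -1,
                                                        1, 3, 4, 6, 7),
                               glu_enriched = 0.12,
                               glu_depleted_offsets = c(-2, 2),
                               glu_depleted = 0.01,
                               arg_enriched_offsets = c(-7, -5, -4, -1, 3),
                               arg_enriched = 0.12,
                               asa_pos_means = list(center = 37.8, near = 33,
                                                    dip = 20, flank = 24),
                               asa_bg_mean = 22,
                               asa_sd = 10,
                               ss_pos = c(H = 0.426, E = 0.044, C = 0.53),
                               ss_bg = c(H = 0.30, E = 0.25, C = 0.45),
                               signal_n = 7L,
                               site_margin = 10L,
                               duplicate_proteins = 0L,
                               seed = 1L) {
  if (is.null(background)) {
    background <- stats::setNames(rep((1 - 0.04 - 0.05) / 18, 20L), AA20)
    background["E"] <- 0.04
    background["R"] <- 0.05
  }
  check_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop(what, " probabilities must be non-negative and sum to 1")
    }
  }
  check_probs(background, "background")
  check_probs(ss_pos, "ss_pos")
  check_probs(ss_bg, "ss_bg")
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            pos_per_protein >= 0L, neg_per_protein >= 0L,
            glu_enriched >= 0, glu_enriched <= 1,
            glu_depleted >= 0, glu_depleted <= 1,
            arg_enriched >= 0, arg_enriched <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 pos_per_protein = as.integer(pos_per_protein),
                 neg_per_protein = as.integer(neg_per_protein),
                 background = background,
                 glu_enriched_offsets = as.integer(glu_enriched_offsets),
                 glu_enriched = glu_enriched,
                 glu_depleted_offsets = as.integer(glu_depleted_offsets),
                 glu_depleted = glu_depleted,
                 arg_enriched_offsets = as.integer(arg_enriched_offsets),
                 arg_enriched = arg_enriched,
                 asa_pos_means = asa_pos_means,
                 asa_bg_mean = asa_bg_mean,
                 asa_sd = asa_sd,
                 ss_pos = ss_pos,
                 ss_bg = ss_bg,
                 signal_n = as.integer(signal_n),
                 site_margin = as.integer(site_margin),
                 duplicate_proteins = as.integer(duplicate_proteins),
                 seed = as.integer(seed)),
            class = "gla_generator_spec")
}

#' Per-offset residue distribution of positive windows
#'
#' The generating distribution at each non-centre offset of a positive
#' window: the background reshaped so Glu (and, at its offsets, Arg) takes
#' the specified probability, the remaining residues rescaled
#' proportionally.
#'
#' @param spec A [gla_generator_spec()].
#' @return `(2 * signal_n + 1) x 20` matrix of probabilities, rows named by
#'   offset; the centre row is a point mass on `E`.
#' @export
positive_position_probs <- function(spec) {
  offsets <- seq.int(-spec$signal_n, spec$signal_n)
  probs <- matrix(0, nrow = length(offsets), ncol = 20L,
                  dimnames = list(as.character(offsets), AA20))
  for (i in seq_along(offsets)) {
    off <- offsets[i]
    if (off == 0L) {
      probs[i, "E"] <- 1
      next
    }
    p <- spec$background
    fixed <- "E"
    p["E"] <- if (off %in% spec$glu_enriched_offsets) {
      spec$glu_enriched
    } else if (off %in% spec$glu_depleted_offsets) {
      spec$glu_depleted
    } else {
      spec$background["E"]
    }
    if (off %in% spec$arg_enriched_offsets) {
      p["R"] <- spec$arg_enriched
      fixed <- c(fixed, "R")
    }
    free <- setdiff(AA20, fixed)
    p[free] <- p[free] / sum(p[free]) * (1 - sum(p[fixed]))
    probs[i, ] <- p
  }
  probs
}

# Pick `k` positions within [margin+1, L-margin], pairwise >= min_gap apart.
place_sites <- function(len, k, margin, min_gap) {
  for (attempt in 1:100) {
    candidates <- seq.int(margin + 1L, len - margin)
    chosen <- integer(0)
    while (length(chosen) < k && length(candidates) > 0L) {
      p <- candidates[sample.int(length(candidates), 1L)]
      chosen <- c(chosen, p)
      candidates <- candidates[abs(candidates - p) >= min_gap]
    }
    if (length(chosen) == k) return(sort(chosen))
  }
  stop("could not place ", k, " sites in a protein of length ", len)
}

rtrunc_norm <- function(n, mean, sd) pmin(100, pmax(0, stats::rnorm(n, mean, sd)))

#' Generate a synthetic carboxylation benchmark
#'
#' Draws protein sequences, plants carboxylated glutamates with the
#' composition/ASA/SS signals of the spec, and optionally writes the full
#' file bundle: `proteins.fasta`, `sites.tsv` (annotated positives),
#' `asa.tsv`, one PSIPRED-style `.ss2` per protein under `ss2/`, and
#' `truth.tsv` labelling every glutamate.
#'
#' @param spec A [gla_generator_spec()].
#' @param dir Output directory, or `NULL` to skip writing files.
#' @return List with `records`, `profiles`, `truth` (data frame
#'   `protein_id`, `position`, `label`), the `spec`, and `dir`.
#' @export
generate_gla_dataset <- function(spec = gla_generator_spec(), dir = NULL) {
  stopifnot(inherits(spec, "gla_generator_spec"))
  pos_probs <- positive_position_probs(spec)
  bg_no_glu <- spec$background
  bg_no_glu["E"] <- 0
  bg_no_glu <- bg_no_glu / sum(bg_no_glu)
  offsets <- seq.int(-spec$signal_n, spec$signal_n)
  asa_means <- numeric(length(offsets))
  asa_means[match(0L, offsets)] <- spec$asa_pos_means$center
  asa_means[offsets %in% c(-1L, 1L)] <- spec$asa_pos_means$near
  asa_means[offsets %in% c(-2L, 2L)] <- spec$asa_pos_means$dip
  asa_means[!(offsets %in% -2:2)] <- spec$asa_pos_means$flank

  result <- with_seed(spec$seed, {
    records <- list()
    profiles <- list()
    for (i in seq_len(spec$n_proteins)) {
      id <- sprintf("SYN%04d", i)
      len <- sample(seq.int(spec$length_range[1], spec$length_range[2]), 1L)
      seq_chars <- sample(AA20, len, replace = TRUE, prob = bg_no_glu)
      n_sites <- spec$pos_per_protein + spec$neg_per_protein
      centers <- if (n_sites > 0L) {
        place_sites(len, n_sites, spec$site_margin, 2L * spec$site_margin + 1L)
      } else integer(0)
      is_pos <- rep(FALSE, n_sites)
      if (spec$pos_per_protein > 0L) {
        is_pos[sample.int(n_sites, spec$pos_per_protein)] <- TRUE
      }
      asa <- rtrunc_norm(len, spec$asa_bg_mean, spec$asa_sd)
      ss <- sample(SS_STATES, len, replace = TRUE, prob = spec$ss_bg)
      for (s in seq_along(centers)) {
        ctr <- centers[s]
        idx <- ctr + offsets
        if (is_pos[s]) {
          for (j in seq_along(offsets)) {
            seq_chars[idx[j]] <- sample(AA20, 1L, prob = pos_probs[j, ])
          }
          asa[idx] <- rtrunc_norm(length(idx), asa_means, spec$asa_sd)
          ss[idx] <- sample(SS_STATES, length(idx), replace = TRUE,
                            prob = spec$ss_pos)
        } else {
          flank <- offsets != 0L
          seq_chars[idx[flank]] <- sample(AA20, sum(flank), replace = TRUE,
                                          prob = spec$background)
          seq_chars[ctr] <- "E"
        }
      }
      seq_chars[centers[is_pos]] <- "E"  # centre is always Glu
      asa <- round(asa, 1)
      rec <- protein_record(id, paste(seq_chars, collapse = ""),
                            sites = centers[is_pos])
      records[[id]] <- rec
      profiles[[id]] <- residue_profile(id, asa, ss, rec$sequence)
    }
    if (spec$duplicate_proteins > 0L) {
      for (i in seq_len(min(spec$duplicate_proteins, spec$n_proteins))) {
        src <- records[[i]]
        id <- paste0(src$id, "_dup")
        records[[id]] <- protein_record(id, src$sequence, sites = src$sites)
        prof <- profiles[[src$id]]
        profiles[[id]] <- residue_profile(id, prof$asa, prof$ss, src$sequence)
      }
    }
    list(records = records, profiles = profiles)
  })
  records <- result$records
  profiles <- result$profiles

  truth <- do.call(rbind, lapply(records, function(rec) {
    hits <- gregexpr("E", rec$sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    data.frame(protein_id = rec$id, position = as.integer(hits),
               label = ifelse(as.integer(hits) %in% rec$sites,
                              "positive", "negative"),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  if (!is.null(dir)) {
    write_gla_dataset(records, profiles, truth, dir)
  }
  list(records = records, profiles = profiles, truth = truth,
       spec = spec, dir = dir)
}

# Write the standard file bundle for a generated dataset.
write_gla_dataset <- function(records, profiles, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ss2"), showWarnings = FALSE)
  fasta <- unlist(lapply(records, function(rec) {
    body <- substring(rec$sequence,
                      seq(1L, nchar(rec$sequence), 60L),
                      pmin(seq(1L, nchar(rec$sequence), 60L) + 59L,
                           nchar(rec$sequence)))
    c(paste0(">", rec$id), body)
  }), use.names = FALSE)
  writeLines(fasta, file.path(dir, "proteins.fasta"))
  sites <- truth[truth$label == "positive", c("protein_id", "position")]
  utils::write.table(sites, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  asa_rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(protein_id = p$protein_id,
               position = seq_along(p$asa),
               asa = formatC(p$asa, format = "f", digits = 1),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(asa_rows, file.path(dir, "asa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (id in names(profiles)) {
    p <- profiles[[id]]
    res <- chars(records[[id]]$sequence)
    conf <- cbind(C = as.numeric(p$ss == "C"),
                  H = as.numeric(p$ss == "H"),
                  E = as.numeric(p$ss == "E"))
    rows <- sprintf("%4d %s %s  %5.3f %5.3f %5.3f",
                    seq_along(p$ss), res, p$ss,
                    conf[, "C"], conf[, "H"], conf[, "E"])
    writeLines(c("# PSF format file", "", rows),
               file.path(dir, "ss2", paste0(id, ".ss2")))
  }
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score predictions against a truth table
#'
#' Joins predictions to the truth table on `(protein_id, position)`; every
#' prediction must match a truth row.
#'
#' @param predictions Data frame with `protein_id`, `position`, `label`.
#' @param truth Truth data frame from [generate_gla_dataset()].
#' @return A [confusion_counts()] object over the predicted sites.
#' @export
truth_eval <- function(predictions, truth) {
  key <- function(df) paste(df$protein_id, df$position, sep = "\r")
  idx <- match(key(predictions), key(truth))
  if (anyNA(idx)) {
    miss <- predictions[is.na(idx), , drop = FALSE]
    stop("prediction(s) not present in the truth table, e.g. ",
         miss$protein_id[1], ":", miss$position[1])
  }
  tally_confusion(truth$label[idx], predictions$label)
}
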