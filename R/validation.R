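#' Validate a profile against labelled control strains
#'
#' Runs the calibrated model over each control's sequence set (nucleotide
#' inputs are six-frame translated first, protein inputs searched directly)
#' and calls a control "detected" when at least one hit reaches the E-value
#' cutoff anywhere in the set.  Positives are expected detected, negatives
#' not; sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param model a calibrated `profile_hmm`.
#' @param controls `data.frame` with columns `strain_label`,
#'   `expected_subclass` (one of LanB, LanM, LanL, LanKC, none), and either
#'   `fasta_path` + `alphabet` (`"dna"`/`"protein"`) or a list-column
#'   `sequences` of sequence sets.  `is_positive` is derived:
#'   positive iff `expected_subclass == "LanB"`.
#' @param config a [search_config()].
#' @return a `validation_report`: list with `per_control` (detected flag and
#'   best E-value per control), the TP/FN/TN/FP counts, `sensitivity` and
#'   `specificity`.  Controls whose file is missing are excluded and
#'   flagged in `per_control$error`, never silently dropped.
#' @export
validate_controls <- function(model, controls, config = search_config()) {
  stopifnot(nrow(controls) >= 2)
  subcl <- c("LanB", "LanM", "LanL", "LanKC", "none")
  if (!all(controls$expected_subclass %in% subcl))
    stop("unknown subclass label: ",
         paste(setdiff(controls$expected_subclass, subcl), collapse = ", "))
  is_pos <- controls$expected_subclass == "LanB"
  if (!any(is_pos)) stop("need at least one positive control")
  if (all(is_pos)) stop("need at least one negative control")

  rows <- lapply(seq_len(nrow(controls)), function(i) {
    out <- data.frame(strain_label = controls$strain_label[i],
                      expected_subclass = controls$expected_subclass[i],
                      is_positive = is_pos[i], detected = NA,
                      best_evalue = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- try({
      seqs <- control_sequences(controls, i)
      targets <- if (identical(attr(seqs, "alphabet"), "dna"))
        six_frame_translate(seqs, config$min_peptide_len) else seqs
      profile_search(model, targets, config)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      out$error <- conditionMessage(attr(res, "condition"))
    } else {
      out$detected <- nrow(res) >= 1L
      out$best_evalue <- if (nrow(res)) min(res$evalue) else NA_real_
    }
    out
  })
  per_control <- do.call(rbind, rows)
  ok <- is.na(per_control$error)
  pos <- per_control$is_positive & ok
  neg <- !per_control$is_positive & ok
  tp <- sum(per_control$detected[pos]); fn <- sum(!per_control$detected[pos])
  fp <- sum(per_control$detected[neg]); tn <- sum(!per_control$detected[neg])
  structure(list(per_control = per_control, true_positives = tp,
                 false_negatives = fn, true_negatives = tn,
                 false_positives = fp,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp)),
            class = "validation_report")
}

control_sequences <- function(controls, i) {
  if ("sequences" %in% names(controls)) return(controls$sequences[[i]])
  path <- controls$fasta_path[i]
  if (!file.exists(path))
    stop("control '", controls$strain_label[i], "': missing file ", path)
  read_fasta(path, controls$alphabet[i] %||% "dna")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n")
  cat(sprintf("  %-30s %-9s %-9s %s\n", "strain", "subclass", "expected",
              "detected"))
  for (i in seq_len(nrow(x$per_control))) {
    r <- x$per_control[i, ]
    verdict <- if (!is.na(r$error)) paste("ERROR:", r$error)
    else if (r$detected) sprintf("yes (E = %.2g)", r$best_evalue) else "no"
    cat(sprintf("  %-30s %-9s %-9s %s\n", r$strain_label,
                r$expected_subclass, if (r$is_positive) "hit" else "no hit",
                verdict))
  }
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d | sensitivity %.3f ",
              x$true_positives, x$false_negatives, x$true_negatives,
              x$false_positives, x$sensitivity))
  cat(sprintf("specificity %.3f\n", x$specificity))
  invisible(x)
}

#' Subclass discrimination table
#'
#' Searches labelled modification proteins and tabulates detections per
#' subclass at the configured cutoff.  A discriminating model detects the
#' targeted family (LanB) and leaves the related subclasses (LanM, LanKC,
#' LanL) undetected.
#'
#' @param model a calibrated `profile_hmm`.
#' @param proteins a protein sequence set (columns `id`, `residues`).
#' @param subclasses character vector (one per protein) with values in
#'   LanB, LanM, LanL, LanKC, none.
#' @param config a [search_config()].
#' @return `data.frame` with columns `subclass`, `n`, `detected`,
#'   `undetected`.
#' @export
subclass_discrimination <- function(model, proteins, subclasses,
                                    config = search_config()) {
  subcl <- c("LanB", "LanM", "LanL", "LanKC", "none")
  if (length(subclasses) && !all(subclasses %in% subcl))
    stop("unknown subclass label: ",
         paste(setdiff(subclasses, subcl), collapse = ", "))
  if (nrow(proteins) == 0L)
    return(data.frame(subclass = character(0), n = integer(0),
                      detected = integer(0), undetected = integer(0)))
  stopifnot(length(subclasses) == nrow(proteins))
  hits <- profile_search(model, proteins, config)
  det <- proteins$id %in% hits$target_id
  out <- do.call(rbind, lapply(unique(subclasses), function(s) {
    sel <- subclasses == s
    data.frame(subclass = s, n = sum(sel), detected = sum(det[sel]),
               undetected = sum(!det[sel]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
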