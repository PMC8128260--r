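#' Consensus-call UID families into supermutants and wild-type UIDs
#'
#' A UID family (all reads sharing one molecular barcode, i.e. one template
#' molecule) is counted as a supermutant only when the mutant base is
#' present in strictly more than \code{consensus_threshold} of its reads;
#' symmetrically for wild-type. Families failing both consensus rules, or
#' with fewer than \code{min_family_reads} reads (a single read carries no
#' error-correction power), are ambiguous and excluded from both counts.
#'
#' @param families data.frame with columns \code{total_reads} and
#'   \code{alt_reads} (one row per UID family).
#' @param min_family_reads minimum reads for a family to be callable.
#' @param consensus_threshold strict consensus fraction; the default 0.9
#'   encodes the ">90% of reads" supermutant rule, so a family at exactly
#'   90% is ambiguous.
#' @return list with \code{n_supermutants}, \code{n_wildtype_uids},
#'   \code{n_ambiguous}.
#' @export
call_families <- function(families, min_family_reads = 2,
                          consensus_threshold = 0.9) {
  if (is.null(families) || nrow(families) == 0)
    stop("no UID families", call. = FALSE)
  if (!all(c("total_reads", "alt_reads") %in% names(families)))
    stop("families table needs columns total_reads, alt_reads", call. = FALSE)
  tot <- families$total_reads
  alt <- families$alt_reads
  if (any(tot < 1) || any(alt < 0) || any(alt > tot))
    stop("invalid family: need 0 <= alt_reads <= total_reads, total_reads >= 1",
         call. = FALSE)
  callable <- tot >= min_family_reads
  frac <- alt / tot
  super <- callable & (frac > consensus_threshold)
  wild <- callable & ((1 - frac) > consensus_threshold)
  list(n_supermutants = sum(super),
       n_wildtype_uids = sum(wild),
       n_ambiguous = sum(!super & !wild))
}

#' Mutant allele fraction from consensus counts
#'
#' MAF is the ratio of supermutant families to wild-type UID families at the
#' interrogated nucleotide. \code{denominator = "total"} switches to the
#' mutant/(mutant + wild-type) convention.
#'
#' @param n_supermutants supermutant family count.
#' @param n_wildtype_uids wild-type UID family count.
#' @param denominator "wildtype" (default, the ratio definition) or "total".
#' @return MAF as a fraction (0 when no supermutants were observed).
#' @export
compute_maf <- function(n_supermutants, n_wildtype_uids,
                        denominator = c("wildtype", "total")) {
  denominator <- match.arg(denominator)
  if (n_supermutants < 0 || n_wildtype_uids < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (n_supermutants == 0) return(0)
  if (n_wildtype_uids == 0)
    stop("no wild-type denominator", call. = FALSE)
  if (denominator == "wildtype") n_supermutants / n_wildtype_uids
  else n_supermutants / (n_supermutants + n_wildtype_uids)
}

#' Permutation positivity test against a control panel
#'
#' Classifies a plasma sample as ctDNA-positive or -negative by comparing
#' its mutation frequency with a panel of tumor-free controls. The null
#' distribution is built by resampling: each permutation draws a
#' pseudo-sample of the test sample's UID depth from the pooled control
#' supermutant frequency (binomial) and computes its MAF. The p-value uses
#' the add-one correction \code{p = (1 + #[null MAF >= observed]) / (B + 1)}
#' so it is never exactly zero; the sample is positive when
#' \code{p < alpha} and at least one supermutant was observed.
#'
#' @param n_supermutants,n_wildtype_uids consensus counts of the test sample.
#' @param controls data.frame of the control panel with columns
#'   \code{supermutants} and \code{wildtype_uids}; at least 5 controls.
#' @param n_permutations number of null draws (default 10000).
#' @param alpha positivity significance level (default 0.01).
#' @param seed optional integer seed for the resampling.
#' @return list: \code{maf}, \code{p_value}, \code{positive},
#'   \code{null_freq} (pooled control supermutant frequency).
#' @export
positivity_test <- function(n_supermutants, n_wildtype_uids, controls,
                            n_permutations = 10000, alpha = 0.01,
                            seed = NULL) {
  if (is.null(controls) || nrow(controls) < 5)
    stop("need at least 5 controls", call. = FALSE)
  if (!all(c("supermutants", "wildtype_uids") %in% names(controls)))
    stop("controls need columns supermutants, wildtype_uids", call. = FALSE)
  depth <- n_supermutants + n_wildtype_uids
  if (depth <= 0) stop("zero depth: no UID families in sample", call. = FALSE)
  ctrl_s <- sum(controls$supermutants)
  ctrl_depth <- ctrl_s + sum(controls$wildtype_uids)
  if (ctrl_depth <= 0) stop("zero depth: control panel is empty", call. = FALSE)
  null_freq <- ctrl_s / ctrl_depth
  obs_maf <- compute_maf(n_supermutants, n_wildtype_uids)
  B <- as.integer(n_permutations)
  p <- with_seed(seed, {
    x <- rbinom(B, depth, null_freq)
    null_maf <- ifelse(x == depth, Inf, x / (depth - x))
    (1 + sum(null_maf >= obs_maf)) / (B + 1)
  })
  list(maf = obs_maf, p_value = p,
       positive = (p < alpha) && n_supermutants >= 1,
       null_freq = null_freq)
}

#' Call every sample in a sample sheet
#'
#' Runs MAF computation and the permutation positivity test over a sample
#' sheet. Counts are taken from the \code{supermutants}/\code{wildtype_uids}
#' columns; rows carrying a \code{family_file} path instead are first
#' consensus-called with \code{\link{call_families}}.
#'
#' @param samples sample sheet data.frame (patient_id, timepoint, day,
#'   supermutants, wildtype_uids and/or family_file).
#' @param controls control panel (see \code{\link{positivity_test}}).
#' @param n_permutations,alpha positivity test settings.
#' @param seed integer seed; each sample gets its own substream.
#' @param min_family_reads,consensus_threshold consensus settings for rows
#'   called from family tables.
#' @return the sample sheet with added columns \code{maf}, \code{p_value},
#'   \code{positive}.
#' @export
call_samples <- function(samples, controls, n_permutations = 10000,
                         alpha = 0.01, seed = 1L,
                         min_family_reads = 2, consensus_threshold = 0.9) {
  if (nrow(samples) == 0) {
    samples$maf <- numeric(0); samples$p_value <- numeric(0)
    samples$positive <- logical(0)
    return(samples)
  }
  if (!"supermutants" %in% names(samples)) samples$supermutants <- NA_integer_
  if (!"wildtype_uids" %in% names(samples)) samples$wildtype_uids <- NA_integer_
  n <- nrow(samples)
  maf <- p_val <- numeric(n)
  pos <- logical(n)
  for (i in seq_len(n)) {
    s <- samples$supermutants[i]
    w <- samples$wildtype_uids[i]
    if ((is.na(s) || is.na(w)) && "family_file" %in% names(samples)) {
      fam <- read_family_table(samples$family_file[i])
      cc <- call_families(fam, min_family_reads, consensus_threshold)
      s <- cc$n_supermutants; w <- cc$n_wildtype_uids
    }
    if (is.na(s) || is.na(w))
      stop(sprintf("sample row %d has neither counts nor family_file", i),
           call. = FALSE)
    res <- positivity_test(s, w, controls, n_permutations, alpha,
                           seed = substream_seed(seed, i))
    samples$supermutants[i] <- s
    samples$wildtype_uids[i] <- w
    maf[i] <- res$maf; p_val[i] <- res$p_value; pos[i] <- res$positive
  }
  samples$maf <- maf
  samples$p_value <- p_val
  samples$positive <- pos
  samples
}

#' Read / write delimited UID-family tables
#'
#' Tab-delimited text with columns family_id, total_reads, alt_reads.
#'
#' @param path file path.
#' @param families data.frame to write.
#' @return \code{read_family_table} returns the data.frame.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("family table not found: %s", path), call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_family_table
#' @export
write_family_table <- function(families, path) {
  utils::write.table(families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
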