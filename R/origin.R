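# Parent-of-origin assignment from trio genotypes of derivative-specific
# sequence near breakpoint junctions. Sites are treated as independent; the
# evidence for a verdict is concordance of all informative sites.

.split_gt <- function(gt) {
  # "A/G", "A|G" or "AG"-style; multiallelic length alleles (STRs) like
  # "12/14" are handled the same way
  strsplit(gt, "[/|]")
}

#' Classify one trio site
#'
#' The derivative-haplotype allele is compared with the parental genotypes:
#' paternal if present only in the father, maternal if only in the mother,
#' uninformative if in both, mendelian_error if in neither.
#'
#' @param der_allele allele observed on the derivative haplotype (character;
#'   SNV bases or STR length alleles).
#' @param father_gt,mother_gt genotypes as `"A/G"`-style strings.
#' @return character vector over sites: `"paternal"`, `"maternal"`,
#'   `"uninformative"` or `"mendelian_error"`.
#' @export
classify_site <- function(der_allele, father_gt, mother_gt) {
  stopifnot(length(der_allele) == length(father_gt),
            length(father_gt) == length(mother_gt))
  f <- .split_gt(father_gt)
  m <- .split_gt(mother_gt)
  vapply(seq_along(der_allele), function(i) {
    in_f <- der_allele[i] %in% f[[i]]
    in_m <- der_allele[i] %in% m[[i]]
    if (in_f && !in_m) "paternal"
    else if (!in_f && in_m) "maternal"
    else if (in_f && in_m) "uninformative"
    else "mendelian_error"
  }, "")
}

#' Aggregate trio sites into a parental-origin verdict
#'
#' The verdict is paternal or maternal only if all informative sites agree;
#' any disagreement yields `"inconsistent"`. Mendelian-error sites are
#' excluded from the vote with a warning and counted separately. Fewer than
#' `min_informative` informative sites yields `"uninformative"`.
#'
#' @param sites `data.frame` with columns `der_allele`, `father_gt`,
#'   `mother_gt` (and optionally `chrom`, `pos`), as read by
#'   [read_trio_sites()].
#' @param min_informative minimum number of informative sites for a verdict.
#' @return list of class `origin_call`: `verdict`, `n_informative`,
#'   `n_paternal`, `n_maternal`, `n_mendelian_error`, `per_site`
#'   (input plus a `call` column).
#' @export
call_origin <- function(sites, min_informative = 1L) {
  stopifnot(is.data.frame(sites),
            all(c("der_allele", "father_gt", "mother_gt") %in% names(sites)))
  calls <- if (nrow(sites)) {
    classify_site(sites$der_allele, sites$father_gt, sites$mother_gt)
  } else character()
  per_site <- cbind(sites, data.frame(call = calls,
                                      stringsAsFactors = FALSE))
  n_err <- sum(calls == "mendelian_error")
  if (n_err > 0) {
    warning(n_err, " mendelian-error site(s) excluded from the origin vote")
  }
  n_pat <- sum(calls == "paternal")
  n_mat <- sum(calls == "maternal")
  n_inf <- n_pat + n_mat
  verdict <- if (n_pat > 0 && n_mat > 0) "inconsistent"
  else if (n_inf < min_informative) "uninformative"
  else if (n_pat > 0) "paternal"
  else "maternal"
  structure(list(verdict = verdict, n_informative = n_inf,
                 n_paternal = n_pat, n_maternal = n_mat,
                 n_mendelian_error = n_err, per_site = per_site),
            class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf(
    "origin_call: %s (%d informative site(s): %d paternal, %d maternal; %d mendelian error(s))\n",
    x$verdict, x$n_informative, x$n_paternal, x$n_maternal,
    x$n_mendelian_error))
  invisible(x)
}

#' Read a trio genotype table
#'
#' TSV with header columns `chrom`, `pos`, `der_allele`, `father_gt`,
#' `mother_gt` (extra columns kept).
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_trio_sites <- function(path) {
  df <- read_results_table(path)
  need <- c("chrom", "pos", "der_allele", "father_gt", "mother_gt")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trio table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$der_allele <- as.character(df$der_allele)
  df$father_gt <- as.character(df$father_gt)
  df$mother_gt <- as.character(df$mother_gt)
  df
}
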