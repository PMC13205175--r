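#' Date the origination of an element along a species ladder
#'
#' Aligns the element against each ladder member (global alignment with free
#' end gaps) and converts percent identity into a presence verdict:
#' `present` at or above `present_threshold`, `absent` at or below
#' `absent_threshold`, `twilight` in between — the band of identity too low
#' to confidently assert homology.  The origination age bracket runs from the
#' age of the oldest species with verdict `present` to the age of the
#' youngest older species whose verdict is not `present` (open upper end when
#' every older species is present).  Species without a locatable ortholog are
#' recorded as `no_data` and take no part in the bracket.
#'
#' The defaults (present >= 55, absent <= 45) are an explicit convention of
#' this package bracketing the usual qualitative judgments (78% clearly
#' significant, 40-45% clearly not); both are configurable and are echoed in
#' the result.
#'
#' @param element the element sequence.
#' @param ladder an [ortholog_ladder()] of candidate homologous regions.
#' @param present_threshold percent identity at or above which the element is
#'   called present.
#' @param absent_threshold percent identity at or below which it is called
#'   absent (must be < `present_threshold`).
#' @param params [alignment_params()].
#' @param identities optional pre-computed per-species identity table
#'   (`data.frame` with `name`, `divergence_age`, `identity_pct`), e.g. from
#'   alignments against external genome data; when given, `element` and the
#'   ladder sequences are not used.
#' @return Object of class `origination_call`: `per_species` data.frame
#'   (`name`, `divergence_age`, `identity_pct`, `verdict`),
#'   `oldest_present_species`, `origination_age_lower`,
#'   `origination_age_upper` (`Inf` = open), and the thresholds used.
#' @examples
#' ids <- data.frame(name = c("lemur", "tree_shrew"),
#'                   divergence_age = c(63, 68),
#'                   identity_pct = c(78, 40))
#' origination_call(identities = ids)
#' @export
origination_call <- function(element = NULL, ladder = NULL,
                             present_threshold = 55, absent_threshold = 45,
                             params = alignment_params(), identities = NULL) {
  if (!(absent_threshold < present_threshold))
    stop("need absent_threshold < present_threshold", call. = FALSE)
  if (is.null(identities)) {
    stopifnot(inherits(ladder, "ortholog_ladder"))
    if (nrow(ladder$members) == 0L) stop("empty ladder", call. = FALSE)
    identities <- data.frame(name = ladder$members$name,
                             divergence_age = ladder$members$divergence_age,
                             identity_pct = NA_real_,
                             stringsAsFactors = FALSE)
    for (i in seq_len(nrow(identities))) {
      s <- ladder$seqs[[i]]
      if (is.null(s)) next
      identities$identity_pct[i] <-
        percent_identity(global_align(element, s, params,
                                      end_gaps_free = TRUE))
    }
  } else {
    identities <- identities[order(identities$divergence_age), , drop = FALSE]
  }
  verdict <- ifelse(is.na(identities$identity_pct), "no_data",
             ifelse(identities$identity_pct >= present_threshold, "present",
             ifelse(identities$identity_pct <= absent_threshold, "absent",
                    "twilight")))
  identities$verdict <- verdict
  present <- which(verdict == "present")
  if (length(present)) {
    oldest <- present[which.max(identities$divergence_age[present])]
    lower <- identities$divergence_age[oldest]
    older_np <- which(identities$divergence_age > lower &
                        verdict %in% c("absent", "twilight"))
    upper <- if (length(older_np)) min(identities$divergence_age[older_np])
             else Inf
    oldest_sp <- identities$name[oldest]
  } else {
    lower <- NA_real_; upper <- NA_real_; oldest_sp <- NA_character_
  }
  structure(list(per_species = identities,
                 oldest_present_species = oldest_sp,
                 origination_age_lower = lower,
                 origination_age_upper = upper,
                 present_threshold = present_threshold,
                 absent_threshold = absent_threshold),
            class = "origination_call")
}

#' @export
print.origination_call <- function(x, ...) {
  cat(sprintf("<origination_call> thresholds: present >= %g%%, absent <= %g%%\n",
              x$present_threshold, x$absent_threshold))
  print(x$per_species, row.names = FALSE)
  if (!is.na(x$origination_age_lower))
    cat(sprintf("originated between %g and %s Mya (oldest present: %s)\n",
                x$origination_age_lower,
                if (is.infinite(x$origination_age_upper)) "an open upper bound"
                else x$origination_age_upper,
                x$oldest_present_species))
  else cat("no species carries the element at the present threshold\n")
  invisible(x)
}
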