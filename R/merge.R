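#' Merge reference-branch and de novo-branch transcript sets
#'
#' Removes cross-branch redundancy with two asymmetric rules, evaluated in
#' a fixed order.  First, a de novo transcript is removed iff some
#' reference-branch transcript covers at least `denovoRemovalCov` of it
#' (minor differences to the genome-anchored sequence make it redundant).
#' Second, a reference transcript is removed only iff some *surviving* de
#' novo transcript covers it completely with an ungapped alignment.
#' Evaluating the de novo rule against the full reference set first is the
#' conservative order: it prefers genome-anchored structures in the final
#' set.
#'
#' @param refTs,denovoTs Named `DNAStringSet` or named character vectors;
#'   ids must be unique across both sets.
#' @param denovoRemovalCov Coverage of the de novo transcript required to
#'   remove it (default 0.95, boundary removed).
#' @param refRemovalCov Coverage of the reference transcript required to
#'   remove it (default 1.0: complete, ungapped).
#' @param minIdentityPct Identity floor for both containment alignments.
#' @param k Seed k-mer length.
#' @return A list with `final` (named character vector of survivors,
#'   reference transcripts first), `keptRef`, `keptDenovo`, and `log` (one
#'   row per removal with rule, coverage and identity evidence).
#' @export
mergeSets <- function(refTs, denovoTs, denovoRemovalCov = 0.95,
                      refRemovalCov = 1.0, minIdentityPct = 90, k = 12L) {
  ref <- if (methods::is(refTs, "XStringSet"))
    stats::setNames(as.character(refTs), names(refTs)) else refTs
  dn <- if (methods::is(denovoTs, "XStringSet"))
    stats::setNames(as.character(denovoTs), names(denovoTs)) else denovoTs
  .checkIds(c(names(ref), names(dn)), "transcript")
  log <- list()
  ## candidate ref partners per de novo transcript via shared k-mers
  partnersOf <- function(qs, ts) {
    kq <- lapply(qs, .canonicalKmers, k = k)
    kt <- lapply(ts, .canonicalKmers, k = k)
    inv <- split(rep(names(ts), lengths(kt)), unlist(kt, use.names = FALSE))
    lapply(kq, function(km) {
      hit <- inv[intersect(km, names(inv))]
      unique(unlist(hit, use.names = FALSE))
    })
  }
  dnPartners <- partnersOf(dn, ref)
  removedDn <- character(0)
  for (id in names(dn)) {
    for (rid in sort(dnPartners[[id]])) {
      h <- ungappedAlignNt(dn[[id]], ref[[rid]], k = k,
                           minIdentityPct = minIdentityPct,
                           queryId = id, targetId = rid,
                           exhaustiveFallback = FALSE)
      if (!is.null(h) && queryCoverage(h) >= denovoRemovalCov) {
        removedDn <- c(removedDn, id)
        log[[length(log) + 1L]] <- data.frame(
          rule = "denovo_covered_by_ref", removedId = id, byId = rid,
          coverage = queryCoverage(h), identity = percentIdentity(h),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  dnKept <- dn[setdiff(names(dn), removedDn)]
  removedRef <- character(0)
  if (length(dnKept)) {
    refPartners <- partnersOf(ref, dnKept)
    for (id in names(ref)) {
      for (did in sort(refPartners[[id]])) {
        h <- ungappedAlignNt(ref[[id]], dnKept[[did]], k = k,
                             minIdentityPct = minIdentityPct,
                             queryId = id, targetId = did,
                             exhaustiveFallback = FALSE)
        if (!is.null(h) && isUngapped(h) &&
            queryCoverage(h) >= refRemovalCov) {
          removedRef <- c(removedRef, id)
          log[[length(log) + 1L]] <- data.frame(
            rule = "ref_covered_by_denovo", removedId = id, byId = did,
            coverage = queryCoverage(h), identity = percentIdentity(h),
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  refKept <- ref[setdiff(names(ref), removedRef)]
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(rule = character(0), removedId = character(0),
               byId = character(0), coverage = numeric(0),
               identity = numeric(0))
  list(final = c(refKept, dnKept), keptRef = refKept, keptDenovo = dnKept,
       log = log)
}
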