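#' Congruence label for one (frequent system, condition) pair
#'
#' Compares the bottleneck call in a frequent-system stratum with the calls
#' in the characteristic strata (method, theme, setting) that the system
#' belongs to.  With `B_sys` the frequent-system call and `B_char` the
#' characteristic-linked call (by default: a bottleneck in at least one of
#' the three matching characteristic strata; with `requireAll`, in all
#' three):
#'
#' * `EPB` (expectedly present): `B_sys` and `B_char`;
#' * `UPB` (unexpectedly present): `B_sys` and not `B_char`;
#' * `UAB` (unexpectedly absent): not `B_sys` but `B_char`;
#' * `concordant_absent`: neither.
#'
#' @param conditionId a condition identifier.
#' @param systemKey a frequent `"method|theme|setting"` key.
#' @param profiles long profile table from [stratumProfiles()], containing
#'   the frequent-system stratum and the three characteristic strata of the
#'   system's levels.
#' @param requireAll use the universal reading of a characteristic-linked
#'   bottleneck (all three characteristic strata) instead of the existential
#'   default.
#' @return list with `label` and `provenance` (the characteristic fields
#'   whose strata carried the bottleneck).
#' @export
labelPair <- function(conditionId, systemKey, profiles, requireAll = FALSE) {
  sysRow <- profiles$stratum_kind == "frequent_system" &
    profiles$stratum_key == systemKey & profiles$condition_id == conditionId
  if (sum(sysRow) != 1L)
    stop("frequent-system stratum profile missing for ", sQuote(systemKey))
  bSys <- profiles$is_bottleneck[sysRow]
  parts <- .splitSystemKey(systemKey)
  bChar <- logical(3)
  fields <- c("method", "theme", "setting")
  names(bChar) <- fields
  for (f in fields) {
    row <- profiles$stratum_kind == f &
      profiles$stratum_key == parts[[f]][1] &
      profiles$condition_id == conditionId
    if (sum(row) != 1L)
      stop(sprintf("characteristic stratum %s:%s missing from profiles",
                   f, parts[[f]][1]))
    bChar[f] <- profiles$is_bottleneck[row]
  }
  linked <- if (requireAll) all(bChar) else any(bChar)
  label <- if (bSys && linked) "EPB"
  else if (bSys) "UPB"
  else if (linked) "UAB"
  else "concordant_absent"
  list(label = label, provenance = fields[bChar])
}

#' Build the congruence matrix over frequent systems
#'
#' Applies [labelPair()] to every (frequent system, condition) pair found in
#' a long profile table, yielding one label per pair plus the provenance of
#' each characteristic-linked call.
#'
#' @param profiles long profile table from [stratumProfiles()] (must contain
#'   the frequent-system strata and all characteristic strata they refer
#'   to).
#' @param requireAll see [labelPair()].
#' @return A [CongruenceMatrix-class].
#' @export
buildCongruenceMatrix <- function(profiles, requireAll = FALSE) {
  systems <- unique(profiles$stratum_key[profiles$stratum_kind == "frequent_system"])
  conditions <- unique(profiles$condition_id)
  lab <- matrix("concordant_absent", length(conditions), length(systems),
                dimnames = list(conditions, systems))
  prov <- list()
  for (s in systems) {
    for (cid in conditions) {
      res <- labelPair(cid, s, profiles, requireAll = requireAll)
      lab[cid, s] <- res$label
      if (length(res$provenance))
        prov[[paste(s, cid, sep = "||")]] <- res$provenance
    }
  }
  new("CongruenceMatrix", labels = lab, provenance = prov,
      requireAll = requireAll)
}

#' @describeIn CongruenceMatrix-class the label matrix (conditions x
#'   frequent systems).
#' @export
setMethod("congruenceLabels", "CongruenceMatrix", function(x) x@labels)

#' @describeIn CongruenceMatrix-class provenance: for each labelled pair
#'   (named `"system||condition"`), the characteristic fields whose strata
#'   carried the bottleneck.
#' @export
setMethod("provenance", "CongruenceMatrix", function(x) x@provenance)

setMethod("show", "CongruenceMatrix", function(object) {
  lab <- object@labels
  cat("CongruenceMatrix:", nrow(lab), "conditions x", ncol(lab),
      "frequent systems",
      if (object@requireAll) "(universal characteristic reading)\n" else "\n")
  tab <- table(factor(lab, levels = c("EPB", "UPB", "UAB", "concordant_absent")))
  cat(sprintf("  EPB: %d  UPB: %d  UAB: %d  concordant absent: %d\n",
              tab["EPB"], tab["UPB"], tab["UAB"], tab["concordant_absent"]))
})

#' @describeIn CongruenceMatrix-class wide export mirroring the shaded-cell
#'   table: rows = conditions, one column per frequent system, cells `EPB`,
#'   `UPB`, `UAB` or empty for concordant absence.
#' @param row.names,optional,... conventional arguments; unused.
#' @export
setMethod("as.data.frame", "CongruenceMatrix",
          function(x, row.names = NULL, optional = FALSE, ...) {
  lab <- x@labels
  lab[lab == "concordant_absent"] <- ""
  data.frame(condition_id = rownames(lab), lab, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
})

#' Summarize the congruence matrix
#'
#' Per frequent system: the number of bottlenecks (`EPB + UPB`), the label
#' counts, the number of condition categories its bottlenecks span, and the
#' number of bottlenecks unique to that system (bottleneck in no other
#' frequent system).  Overall: the total bottleneck count and the mean and
#' range of each per-system count.
#'
#' @param matrix a [CongruenceMatrix-class].
#' @param registry the [ConditionRegistry-class] (for category membership).
#' @return list with `perSystem` (data.frame) and `overall` (list with
#'   `total_bottlenecks`, `pct_EPB`, `pct_UPB`, and `mean`/`min`/`max` of
#'   the per-system counts).
#' @export
congruenceSummary <- function(matrix, registry) {
  lab <- congruenceLabels(matrix)
  isB <- lab %in% c("EPB", "UPB")
  dim(isB) <- dim(lab)
  dimnames(isB) <- dimnames(lab)
  cat2 <- stats::setNames(registry@conditions$category,
                          registry@conditions$condition_id)
  perSystem <- data.frame(
    system = colnames(lab),
    n_bottlenecks = as.integer(colSums(isB)),
    n_EPB = as.integer(colSums(lab == "EPB")),
    n_UPB = as.integer(colSums(lab == "UPB")),
    n_UAB = as.integer(colSums(lab == "UAB")),
    n_categories = vapply(seq_len(ncol(lab)), function(j) {
      length(unique(cat2[rownames(lab)[isB[, j]]]))
    }, integer(1)),
    n_unique = vapply(seq_len(ncol(lab)), function(j) {
      others <- isB[, -j, drop = FALSE]
      sum(isB[, j] & rowSums(others) == 0)
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  total <- sum(perSystem$n_bottlenecks)
  rng <- function(v) {
    if (!length(v))
      return(list(mean = NA_real_, min = NA_real_, max = NA_real_))
    list(mean = mean(v), min = min(v), max = max(v))
  }
  overall <- list(
    total_bottlenecks = total,
    total_EPB = sum(perSystem$n_EPB),
    total_UPB = sum(perSystem$n_UPB),
    total_UAB = sum(perSystem$n_UAB),
    pct_EPB = if (total) 100 * sum(perSystem$n_EPB) / total else NA_real_,
    pct_UPB = if (total) 100 * sum(perSystem$n_UPB) / total else NA_real_,
    bottlenecks_per_system = rng(perSystem$n_bottlenecks),
    EPB_per_system = rng(perSystem$n_EPB),
    UPB_per_system = rng(perSystem$n_UPB),
    UAB_per_system = rng(perSystem$n_UAB),
    categories_per_system = rng(perSystem$n_categories),
    n_bottleneck_conditions = sum(rowSums(isB) > 0)
  )
  list(perSystem = perSystem, overall = overall)
}
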