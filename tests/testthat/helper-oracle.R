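# Independent brute-force oracle: re-derives flags, stratum calls and
# congruence labels from the raw survey with plain double loops.  Kept free
# of the package's vectorized code paths on purpose.

oracleFlagMatrices <- function(survey) {
  r <- ratings(survey)
  sel <- importanceSelections(survey)
  p <- nrow(r); n <- ncol(r)
  sub <- imp <- bot <- matrix(FALSE, p, n, dimnames = dimnames(r))
  for (j in seq_len(n)) {
    for (i in seq_len(p)) {
      v <- r[i, j]
      sub[i, j] <- !is.na(v) && v != 5
      imp[i, j] <- rownames(r)[i] %in% sel[[j]]
      bot[i, j] <- sub[i, j] && imp[i, j]
    }
  }
  list(suboptimal = sub, important = imp, bottleneck = bot)
}

oracleStratumCalls <- function(survey, bottleneck, minCount = 10,
                               threshold = 0.10) {
  cd <- as.data.frame(SummarizedExperiment::colData(survey))
  keys <- paste(cd$method, cd$theme, cd$setting, sep = "|")
  frequent <- character()
  for (k in unique(keys)) if (sum(keys == k) > minCount) frequent <- c(frequent, k)
  strata <- list()
  for (k in frequent)
    strata[[length(strata) + 1L]] <- list(kind = "frequent_system", key = k,
                                          idx = which(keys == k))
  for (f in c("method", "theme", "setting"))
    for (lev in unique(cd[[f]]))
      strata[[length(strata) + 1L]] <- list(kind = f, key = lev,
                                            idx = which(cd[[f]] == lev))
  strata[[length(strata) + 1L]] <- list(kind = "all", key = "all",
                                        idx = seq_len(nrow(cd)))
  rows <- list()
  for (s in strata) {
    for (i in seq_len(nrow(bottleneck))) {
      nf <- 0L
      for (j in s$idx) if (bottleneck[i, j]) nf <- nf + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        stratum_kind = s$kind, stratum_key = s$key,
        condition_id = rownames(bottleneck)[i],
        n_members = length(s$idx), n_flagged = nf,
        is_bottleneck = nf / length(s$idx) > threshold + 1e-12,
        stringsAsFactors = FALSE)
    }
  }
  list(frequent = frequent, calls = do.call(rbind, rows))
}

oracleCongruenceLabels <- function(calls, frequent, conditions) {
  pick <- function(kind, key, cid) {
    v <- calls$is_bottleneck[calls$stratum_kind == kind &
                               calls$stratum_key == key &
                               calls$condition_id == cid]
    length(v) == 1L && v
  }
  labs <- list()
  for (k in frequent) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    for (cid in conditions) {
      bSys <- pick("frequent_system", k, cid)
      bChar <- pick("method", parts[1], cid) ||
        pick("theme", parts[2], cid) ||
        pick("setting", parts[3], cid)
      labs[[paste(k, cid, sep = "||")]] <-
        if (bSys && bChar) "EPB"
        else if (bSys) "UPB"
        else if (bChar) "UAB"
        else "concordant_absent"
    }
  }
  labs
}
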