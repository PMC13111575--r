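# exact largest-remainder apportionment of n units over fractions;
# remainder ties broken by position (callers pass a seeded shuffle order)
.largestRemainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    rem <- q - base
    extra <- order(-rem)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Patient-level train/validation/test split
#'
#' The unit of assignment is the case id, never the view or laterality, so
#' all images of one patient land in exactly one split — the leakage-safe
#' protocol for medical imaging cohorts. Within each label stratum the case
#' ids are shuffled with the seed and apportioned by largest remainder, so
#' split sizes are exact to within one case per stratum. Default fractions
#' are 75/12/13 (train/validation/test).
#'
#' @param manifest manifest data frame (`case_id`, `label` columns used).
#' @param fractions named or positional numeric of length 3
#'   (train, val, test) summing to 1.
#' @param stratifyByLabel stratify by the case label (default `TRUE`).
#' @param seed shuffle seed.
#' @return a list of class `SplitPlan`: `fractions`, `seed`, `stratified`,
#'   and `assignment` — a data.frame with one row per case id and its split.
#' @examples
#' coh <- generateCohort(50, seed = 3)
#' plan <- patientLevelSplit(coh$manifest, seed = 3)
#' table(plan$assignment$split)
#' @export
patientLevelSplit <- function(manifest, fractions = c(train = 0.75,
                                                      val = 0.12,
                                                      test = 0.13),
                              stratifyByLabel = TRUE, seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9)
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  cases <- unique(manifest[, c("case_id", "label")])
  if (anyDuplicated(cases$case_id))
    stop("conflicting labels within a case; validate the manifest first")
  strata <- if (stratifyByLabel) split(cases$case_id, cases$label)
            else list(all = cases$case_id)
  if (stratifyByLabel) {
    small <- names(strata)[vapply(strata, length, 1L) < 3]
    if (length(small))
      stop("stratum(s) with fewer than 3 cases: ",
           paste(small, collapse = ", "),
           "; add cases or use stratifyByLabel = FALSE")
  }
  assignment <- .withSeed(seed, {
    out <- lapply(strata, function(ids) {
      ids <- sample(ids)
      sizes <- .largestRemainder(length(ids), fractions)
      data.frame(case_id = ids, split = rep(names(fractions), sizes),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  assignment <- assignment[order(assignment$case_id), ]
  rownames(assignment) <- NULL
  structure(list(fractions = fractions, seed = seed,
                 stratified = stratifyByLabel, assignment = assignment),
            class = "SplitPlan")
}

#' Attach a split plan to a manifest
#'
#' @param manifest manifest data frame.
#' @param plan a `SplitPlan` from [patientLevelSplit()].
#' @return the manifest with a `split` column; every view inherits its
#'   case's split.
#' @export
applySplit <- function(manifest, plan) {
  stopifnot(inherits(plan, "SplitPlan"))
  idx <- match(manifest$case_id, plan$assignment$case_id)
  if (anyNA(idx)) stop("plan does not cover all case ids in the manifest")
  manifest$split <- plan$assignment$split[idx]
  manifest
}

#' Audit a split assignment for patient-level leakage
#'
#' Checks a per-row split assignment for the three leakage patterns:
#' (b) CC/MLO views of one breast landing in different splits,
#' (c) left/right breasts of one case split apart, and
#' (a) any residual same-case multi-split occurrence not already explained
#' by (b) or (c). The types are mutually exclusive; an empty report means
#' the assignment is leakage-safe.
#'
#' @param manifest manifest data frame with a `split` column (e.g. from
#'   [applySplit()], or any hand-built assignment to audit).
#' @return a data.frame of violations with columns `type` (`"a"`, `"b"`,
#'   `"c"`), `case_id`, `detail`; zero rows when leakage-safe.
#' @export
auditLeakage <- function(manifest) {
  if (!"split" %in% names(manifest))
    stop("manifest has no 'split' column to audit")
  v <- list()
  # (b) one breast (case + laterality) across splits
  breast <- paste(manifest$case_id, manifest$laterality, sep = "|")
  nb <- tapply(manifest$split, breast, function(s) length(unique(s)))
  bad_b <- names(nb)[nb > 1]
  for (b in bad_b) {
    parts <- strsplit(b, "|", fixed = TRUE)[[1]]
    rows <- breast == b
    v[[length(v) + 1]] <- data.frame(
      type = "b", case_id = parts[1],
      detail = sprintf("views of breast %s span splits: %s", parts[2],
                       paste(sort(unique(manifest$split[rows])),
                             collapse = ",")))
  }
  caseB <- unique(sub("\\|.*", "", bad_b))
  # (c) lateralities of one case split apart (each breast internally
  # consistent, otherwise it is a type-b case)
  for (cid in unique(manifest$case_id)) {
    rows <- manifest$case_id == cid
    if (cid %in% caseB) next
    lat <- manifest$laterality[rows]
    if (length(unique(lat)) < 2) next
    persplit <- tapply(manifest$split[rows], lat, function(s) unique(s)[1])
    if (length(unique(persplit)) > 1)
      v[[length(v) + 1]] <- data.frame(
        type = "c", case_id = cid,
        detail = sprintf("lateralities split apart: %s",
                         paste(names(persplit), persplit, sep = "=",
                               collapse = ", ")))
  }
  caseC <- vapply(v, function(x) x$case_id[1], "")[
    vapply(v, function(x) x$type[1], "") == "c"]
  # (a) residual same-case multi-split not flagged above
  ncs <- tapply(manifest$split, manifest$case_id, function(s) length(unique(s)))
  for (cid in names(ncs)[ncs > 1]) {
    if (cid %in% caseB || cid %in% caseC) next
    v[[length(v) + 1]] <- data.frame(
      type = "a", case_id = cid,
      detail = "case appears in multiple splits")
  }
  if (length(v) == 0)
    return(data.frame(type = character(0), case_id = character(0),
                      detail = character(0)))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
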