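#' The NPC clinical severity scale (NIH scale minus hearing)
#'
#' The composite severity score used throughout this package is the NIH
#' Niemann-Pick type C clinical severity scale with the hearing domain
#' removed (hearing is not comparably measured across centres). It comprises
#' 8 major neurological domains scored 0--5 and 8 minor domains scored 0--2,
#' so the theoretical maximum is 40 over the majors and 56 overall.
#'
#' @return A data.frame with one row per domain and columns `domain`,
#'   `tier` (`"major"` or `"minor"`) and `max_score`.
#' @examples
#' d <- npc_domains()
#' sum(d$max_score)                       # 56
#' sum(d$max_score[d$tier == "major"])    # 40
#' @export
npc_domains <- function() {
  data.frame(
    domain = c(
      "eye_movement", "ambulation", "memory", "speech", "swallowing",
      "fine_motor_skills", "cognition", "seizures",
      "cataplexy", "behavioural_changes", "narcolepsy",
      "psychiatric_symptoms", "hyperreflexia", "incontinence", "abr",
      "respiratory_signs"
    ),
    tier = rep(c("major", "minor"), each = 8L),
    max_score = rep(c(5L, 2L), each = 8L),
    stringsAsFactors = FALSE
  )
}

#' Names of the major severity domains
#' @return Character vector of the 8 major domain names.
#' @export
major_domains <- function() {
  d <- npc_domains()
  d$domain[d$tier == "major"]
}

#' Names of the minor severity domains
#' @return Character vector of the 8 minor domain names.
#' @export
minor_domains <- function() {
  d <- npc_domains()
  d$domain[d$tier == "minor"]
}

# internal: named vector of per-domain maxima
domain_maxima <- function() {
  d <- npc_domains()
  stats::setNames(d$max_score, d$domain)
}

check_excluded <- function(excluded) {
  excluded <- as.character(excluded)
  unknown <- setdiff(excluded, npc_domains()$domain)
  if (length(unknown) > 0L) {
    stop("unknown domain(s) in `exclude`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  excluded
}

#' Total composite severity of one or more visits
#'
#' Sums the per-domain scores of each visit, optionally leaving out a set of
#' domains (for reduced panels or scale variants, e.g. seizure-free scoring).
#' Scores must be integers within each domain's range; violations raise an
#' error -- use [validate_visits()] to collect them instead.
#'
#' @param visits A data.frame with one row per visit and one column per
#'   domain of [npc_domains()] (additional columns are ignored).
#' @param exclude Character vector of domain names to omit from the total.
#' @return Integer vector of severity totals, one per row of `visits`.
#' @examples
#' v <- as.data.frame(as.list(stats::setNames(rep(0, 16), npc_domains()$domain)))
#' v$ambulation <- 5
#' total_severity(v)                      # 5
#' total_severity(v, exclude = "ambulation")  # 0
#' @export
total_severity <- function(visits, exclude = character()) {
  exclude <- check_excluded(exclude)
  bad <- validate_visits(visits)
  if (nrow(bad) > 0L) {
    stop("invalid subdomain scores (", nrow(bad), " violation(s)); ",
         "first: row ", bad$row[1L], ", ", bad$domain[1L], " = ",
         bad$value[1L], " (allowed ", bad$allowed[1L], ")", call. = FALSE)
  }
  keep <- setdiff(npc_domains()$domain, exclude)
  if (length(keep) == 0L) {
    return(rep(0L, nrow(visits)))
  }
  as.integer(round(rowSums(visits[, keep, drop = FALSE])))
}

#' Validate per-domain scores of a visit table
#'
#' Checks that every domain column is present and every score is a
#' non-negative integer no larger than its domain maximum. Violations are
#' returned, not thrown, so a whole file can be screened in one pass.
#'
#' @param visits A data.frame with one column per domain.
#' @return A data.frame with columns `row`, `domain`, `value`, `allowed`;
#'   zero rows when all scores are valid.
#' @export
validate_visits <- function(visits) {
  maxima <- domain_maxima()
  missing <- setdiff(names(maxima), names(visits))
  if (length(missing) > 0L) {
    stop("missing domain column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (dom in names(maxima)) {
    v <- visits[[dom]]
    ok <- !is.na(v) & v >= 0 & v <= maxima[[dom]] & v == round(v)
    if (any(!ok)) {
      out[[dom]] <- data.frame(
        row = which(!ok), domain = dom, value = v[!ok],
        allowed = sprintf("integer 0..%d", maxima[[dom]]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(row = integer(), domain = character(),
                      value = numeric(), allowed = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$row), , drop = FALSE]
}
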