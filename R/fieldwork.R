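# RDD fieldwork simulation: number draws, call attempts, Kish selection,
# cooperation, AAPOR disposition coding.

DISPOSITION_CODES <- c("I", "P", "R", "NC", "O", "UH", "UO", "NE")

#' Fieldwork configuration
#'
#' @param n_ll,n_cell numbers of landline and cell numbers drawn from the
#'   frames.  `dialed_budget` with `ll_share` offers the conventional 40/60
#'   landline/cell allocation instead: `n_ll = ll_share * dialed_budget`.
#' @param dialed_budget optional total number of dialed numbers.
#' @param ll_share landline share of the dialed budget (default 0.40).
#' @param max_call_attempts maximum call attempts per number (>= 1).
#' @param seed integer seed for the fieldwork randomness.
#' @return a `fieldwork_config` list.
#' @export
fieldwork_config <- function(n_ll = NULL, n_cell = NULL,
                             dialed_budget = NULL, ll_share = 0.40,
                             max_call_attempts = 20L, seed = 1L) {
  if (!is.null(dialed_budget)) {
    n_ll <- as.integer(round(ll_share * dialed_budget))
    n_cell <- as.integer(dialed_budget) - n_ll
  }
  if (is.null(n_ll) || is.null(n_cell)) {
    stop("supply n_ll and n_cell, or dialed_budget", call. = FALSE)
  }
  if (max_call_attempts < 1) stop("max_call_attempts must be >= 1", call. = FALSE)
  structure(list(n_ll = as.integer(n_ll), n_cell = as.integer(n_cell),
                 max_call_attempts = as.integer(max_call_attempts),
                 seed = as.integer(seed)),
            class = "fieldwork_config")
}

#' Draw telephone numbers from the frames
#'
#' Simple random sampling without replacement within each frame.
#'
#' @param frames a `frame_spec` from [build_frames()].
#' @param config a [fieldwork_config()].
#' @return list with integer vectors `ll` and `cell` of dialed number ids.
#' @export
draw_numbers <- function(frames, config) {
  stopifnot(inherits(frames, "frame_spec"), inherits(config, "fieldwork_config"))
  if (config$n_ll > frames$N_ll || config$n_cell > frames$N_cell) {
    stop("sample size exceeds frame size", call. = FALSE)
  }
  list(ll = sort(sample.int(frames$N_ll, config$n_ll)),
       cell = sort(sample.int(frames$N_cell, config$n_cell)))
}

#' Kish within-household respondent selection
#'
#' Draws the person to interview among the eligible household members, with
#' the same probability `1/e` for each.
#'
#' @param eligible_ids vector of eligible member ids; must be nonempty.
#' @return one element of `eligible_ids`.
#' @export
kish_select <- function(eligible_ids) {
  if (length(eligible_ids) == 0) {
    stop("no eligible member: household is ineligible", call. = FALSE)
  }
  eligible_ids[sample.int(length(eligible_ids), 1L)]
}

#' Simulate the call process on dialed numbers
#'
#' Non-working numbers are coded ineligible (NE).  For working numbers a
#' truncated-geometric contact process runs up to `max_call_attempts`; a
#' configurable fraction of never-answered numbers is coded unknown
#' eligibility (UH), the rest non-contact (NC).  On the cell frame the
#' interviewee is the number's owner.  On the landline frame the answerer is
#' drawn uniformly among household members, the interviewee by Kish selection
#' among the eligible members; when the selectee is not the answerer an extra
#' attempt is needed and succeeds with the configured recontact probability.
#' Cooperation yields a complete interview (I), a partial (P) with small
#' probability, or a refusal (R).
#'
#' @param dialed list from [draw_numbers()].
#' @param population a `synthetic_population`.
#' @param frames a `frame_spec`.
#' @param config a [fieldwork_config()].
#' @param full_response if `TRUE`, all contact and cooperation probabilities
#'   are forced to 1 and no numbers are coded unknown: every dialed working
#'   number yields a complete interview (used for design-unbiasedness
#'   checks).
#' @return list with `respondents` (one row per complete interview),
#'   `dispositions` (counts per frame and AAPOR code) and `call_log`
#'   (per dialed number: frame, code, attempts).
#' @export
simulate_calls <- function(dialed, population, frames, config,
                           full_response = FALSE) {
  stopifnot(inherits(population, "synthetic_population"),
            inherits(frames, "frame_spec"),
            inherits(config, "fieldwork_config"))
  set.seed(child_seed(config$seed, "fieldwork"))
  persons <- population$persons
  rmod <- population$config$response_model
  A <- config$max_call_attempts

  contact_attempt <- function(p, m) {
    # attempt index of first contact under per-attempt probability p,
    # truncated at A (NA_integer_ = never contacted)
    if (full_response) return(rep(1L, m))
    g <- rgeom(m, pmin(pmax(p, 1e-12), 1)) + 1L
    g[g > A] <- NA_integer_
    g
  }
  cooperation <- function(p_coop, m) {
    if (full_response) return(rep("I", m))
    u <- runif(m)
    ifelse(u < p_coop, "I",
           ifelse(u < p_coop + rmod$partial_prob, "P", "R"))
  }
  unknown_or_nc <- function(m) {
    if (full_response || m == 0) return(rep("NC", m))
    ifelse(runif(m) < rmod$unknown_frac, "UH", "NC")
  }

  ## --- cell frame: one-stage, interviewee is the owner -------------------
  cnum <- frames$cell[dialed$cell, , drop = FALSE]
  n_c <- nrow(cnum)
  code_c <- rep("NE", n_c)
  att_c <- rep(1L, n_c)
  pid_c <- rep(NA_integer_, n_c)
  wk <- which(cnum$working)
  if (length(wk)) {
    owner <- cnum$owner_id[wk]
    fc <- contact_attempt(persons$contact_cell[owner], length(wk))
    nc <- is.na(fc)
    code_c[wk[nc]] <- unknown_or_nc(sum(nc))
    att_c[wk[nc]] <- A
    hit <- wk[!nc]
    if (length(hit)) {
      cc <- cooperation(persons$coop_cell[owner[!nc]], length(hit))
      code_c[hit] <- cc
      att_c[hit] <- fc[!nc]
      pid_c[hit] <- owner[!nc]
    }
  }

  ## --- landline frame: two-stage with Kish selection ---------------------
  lnum <- frames$ll[dialed$ll, , drop = FALSE]
  n_l <- nrow(lnum)
  code_l <- rep("NE", n_l)
  att_l <- rep(1L, n_l)
  pid_l <- rep(NA_integer_, n_l)
  kish_mismatch <- 0L
  wk <- which(lnum$working)
  if (length(wk)) {
    hhid <- lnum$owner_id[wk]
    hh <- population$households
    p_contact <- hh$contact_landline[match(hhid, hh$household_id)]
    fc <- contact_attempt(p_contact, length(wk))
    nc <- is.na(fc)
    code_l[wk[nc]] <- unknown_or_nc(sum(nc))
    att_l[wk[nc]] <- A
    hit <- which(!nc)
    members_by_hh <- split(persons$person_id, persons$household_id)
    for (j in hit) {
      members <- members_by_hh[[as.character(hhid[j])]]
      answerer <- members[sample.int(length(members), 1L)]
      selectee <- kish_select(members)  # all generated persons are eligible
      attempts <- fc[j]
      reached <- TRUE
      if (selectee != answerer) {
        kish_mismatch <- kish_mismatch + 1L
        attempts <- attempts + 1L
        reached <- full_response ||
          (attempts <= A && runif(1) < rmod$recontact_prob)
      }
      k <- wk[j]
      if (!reached) {
        code_l[k] <- "NC"
        att_l[k] <- min(attempts, A)
      } else {
        code_l[k] <- cooperation(persons$coop_landline[selectee], 1L)
        att_l[k] <- attempts
        pid_l[k] <- selectee
      }
    }
  }

  call_log <- rbind(
    data.frame(frame = "landline", number_id = lnum$number_id,
               code = code_l, attempts = att_l, person_id = pid_l),
    data.frame(frame = "cell", number_id = cnum$number_id,
               code = code_c, attempts = att_c, person_id = pid_c)
  )
  # completes keep their interviewee; other codes carry no respondent
  call_log$person_id[call_log$code != "I"] <- NA_integer_

  respondents <- build_respondents(call_log, persons,
                                   population$config$misreport_prob)
  dispositions <- disposition_table(call_log)

  structure(list(respondents = respondents, dispositions = dispositions,
                 call_log = call_log,
                 kish_mismatch_rate = if (n_l) kish_mismatch /
                   max(1L, sum(code_l %in% c("I", "P", "R"))) else NA_real_),
            class = "fieldwork_result")
}

build_respondents <- function(call_log, persons, misreport_prob = 0) {
  done <- call_log[call_log$code == "I", , drop = FALSE]
  rec <- persons[match(done$person_id, persons$person_id), , drop = FALSE]
  rec$frame_of_origin <- done$frame
  rec$attempts <- done$attempts
  rec$t_ll <- rec$n_landline
  rec$t_cell <- rec$n_cell
  if (misreport_prob > 0 && nrow(rec)) {
    # questionnaire-reported counts can be off by one; the count for the
    # frame that produced the interview stays >= 1
    jitter <- function(t, floor_) {
      hit <- runif(length(t)) < misreport_prob
      pmax(t + hit * sample(c(-1L, 1L), length(t), TRUE), floor_)
    }
    rec$t_ll <- jitter(rec$t_ll, as.integer(rec$frame_of_origin == "landline"))
    rec$t_cell <- jitter(rec$t_cell, as.integer(rec$frame_of_origin == "cell"))
  }
  rownames(rec) <- NULL
  rec
}

disposition_table <- function(call_log) {
  out <- expand.grid(frame = c("landline", "cell"), code = DISPOSITION_CODES,
                     stringsAsFactors = FALSE)
  tab <- table(factor(call_log$frame, c("landline", "cell")),
               factor(call_log$code, DISPOSITION_CODES))
  out$count <- as.vector(tab[cbind(out$frame, out$code)])
  out[order(out$frame, match(out$code, DISPOSITION_CODES)), ]
}

#' @export
print.fieldwork_result <- function(x, ...) {
  n_i <- sum(x$dispositions$count[x$dispositions$code == "I"])
  cat(sprintf("Fieldwork: %d dialed numbers, %d complete interviews\n",
              sum(x$dispositions$count), n_i))
  by_frame <- tapply(x$respondents$attempts, x$respondents$frame_of_origin, mean)
  cat("  mean attempts per complete:",
      paste(sprintf("%s %.1f", names(by_frame), by_frame), collapse = ", "), "\n")
  invisible(x)
}
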