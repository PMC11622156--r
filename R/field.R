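#' A single 24-2 visual field
#'
#' Constructs a `vf_field`: one eye's 24-2 test with one stimulus size.
#' Sensitivities are stored as a named numeric vector over the 52
#' non-blind-spot locations of that eye's grid, in the canonical grid order
#' of [vf_grid_seeing()]. Values must be non-negative; the instrument's
#' "<0" floor token is handled by the CSV reader, which maps it to 0 dB.
#'
#' @param subject_id,session_id opaque identifiers; `session_id` groups the
#'   same-day size III / size V tests of one eye.
#' @param cohort `"GLAUCOMA"` or `"NAION"`.
#' @param eye `"OD"` or `"OS"`.
#' @param stimulus Goldmann stimulus size, `"III"` or `"V"` (tokens `"3"`
#'   and `"5"` are accepted, case-insensitively).
#' @param age_years age at test, in years.
#' @param sensitivities numeric vector of length 52 named by location key
#'   (`"x:y"`), or an unnamed length-52 vector taken to be in canonical
#'   grid order. dB, in \[0, 50\].
#' @return An object of class `vf_field`.
#' @export
vf_field <- function(subject_id, cohort, eye, session_id, stimulus,
                     age_years, sensitivities) {
  eye <- match.arg(toupper(eye), c("OD", "OS"))
  cohort <- match.arg(toupper(cohort), c("GLAUCOMA", "NAION"))
  stimulus <- normalize_stimulus(stimulus)
  stopifnot(is.numeric(age_years), length(age_years) == 1L, age_years > 0)
  keys <- vf_grid_seeing(eye)$loc
  if (is.null(names(sensitivities))) {
    if (length(sensitivities) != 52L)
      stop("unnamed sensitivities must have length 52", call. = FALSE)
    names(sensitivities) <- keys
  }
  missing <- setdiff(keys, names(sensitivities))
  if (length(missing))
    stop(sprintf("field %s/%s/%s/%s: missing location(s) %s",
                 subject_id, eye, session_id, stimulus,
                 paste0("(", sub(":", ", ", missing), ")", collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(names(sensitivities)))
    stop("duplicate locations in sensitivities", call. = FALSE)
  sens <- as.numeric(sensitivities[keys])
  names(sens) <- keys
  if (any(!is.finite(sens)) || any(sens < 0) || any(sens > 50))
    stop("sensitivities must be finite dB values in [0, 50]", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         cohort = cohort, eye = eye,
         session_id = as.character(session_id),
         stimulus = stimulus, age_years = as.numeric(age_years),
         sens = sens),
    class = "vf_field")
}

#' @export
print.vf_field <- function(x, ...) {
  cat(sprintf("<vf_field> subject %s  %s  session %s  stimulus %s  age %.1f\n",
              x$subject_id, x$eye, x$session_id, x$stimulus, x$age_years))
  cat(sprintf("  sensitivities: %d locations, %.0f-%.0f dB (mean %.1f)\n",
              length(x$sens), min(x$sens), max(x$sens), mean(x$sens)))
  invisible(x)
}

#' Normalize a stimulus-size token
#'
#' Accepts the common export variants `"III"`, `"3"`, `"V"`, `"5"`
#' (case-insensitive) and returns `"III"` or `"V"`.
#'
#' @param token character or numeric stimulus token.
#' @return `"III"` or `"V"`.
#' @export
normalize_stimulus <- function(token) {
  t <- toupper(trimws(as.character(token)))
  if (t %in% c("III", "3")) return("III")
  if (t %in% c("V", "5")) return("V")
  stop(sprintf("unknown stimulus token '%s' (expected III/3/V/5)", token),
       call. = FALSE)
}

#' A same-day size III / size V field pair
#'
#' Binds two [vf_field()]s into a `vf_pair`. The two fields must agree on
#' subject, eye, session and age, and carry stimulus III and V respectively.
#'
#' @param field_III,field_V `vf_field` objects with stimulus III and V.
#' @return An object of class `vf_pair`.
#' @export
vf_pair <- function(field_III, field_V) {
  stopifnot(inherits(field_III, "vf_field"), inherits(field_V, "vf_field"))
  if (field_III$stimulus != "III" || field_V$stimulus != "V")
    stop("vf_pair() needs a size III field and a size V field, in that order",
         call. = FALSE)
  same <- c("subject_id", "eye", "session_id", "age_years", "cohort")
  for (f in same)
    if (!identical(field_III[[f]], field_V[[f]]))
      stop(sprintf("paired fields disagree on %s (%s vs %s)",
                   f, field_III[[f]], field_V[[f]]), call. = FALSE)
  structure(list(field_III = field_III, field_V = field_V), class = "vf_pair")
}

#' @export
print.vf_pair <- function(x, ...) {
  cat(sprintf("<vf_pair> subject %s  %s  session %s  age %.1f (III + V)\n",
              x$field_III$subject_id, x$field_III$eye,
              x$field_III$session_id, x$field_III$age_years))
  invisible(x)
}

#' Read visual fields from a long-format CSV
#'
#' Reads a UTF-8 comma-separated table with one row per tested location and
#' columns `subject_id`, `cohort`, `eye`, `session_id`, `stimulus`,
#' `age_years`, `x_deg`, `y_deg`, `sensitivity_db`, and assembles one
#' [vf_field()] per `(subject, eye, session, stimulus)` group. Rows at the
#' two blind-spot locations are dropped (their count is reported via
#' `message()`), and the instrument floor token `"<0"` is parsed as 0 dB.
#'
#' @param path path to the CSV file.
#' @param schema_config optional list of schema hooks. Currently only
#'   `reliability_filter`, a predicate applied to each assembled field
#'   (fields for which it returns `FALSE` are dropped); the default keeps
#'   everything, as no reliability indices are part of the schema.
#' @return A list of `vf_field` objects.
#' @seealso [write_vf_fields()] for the inverse, [pair_same_day()] to form
#'   pairs.
#' @export
read_vf_fields <- function(path, schema_config = list()) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  need <- c("subject_id", "cohort", "eye", "session_id", "stimulus",
            "age_years", "x_deg", "y_deg", "sensitivity_db")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("fields CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sens_chr <- trimws(raw$sensitivity_db)
  sub_floor <- grepl("^<\\s*0$", sens_chr)
  sens <- suppressWarnings(as.numeric(sens_chr))
  sens[sub_floor] <- 0
  if (anyNA(sens))
    stop("unparseable sensitivity value(s), e.g. '",
         sens_chr[which(is.na(sens))[1]], "'", call. = FALSE)
  raw$.sens <- pmax(sens, 0)
  raw$.x <- as.integer(raw$x_deg)
  raw$.y <- as.integer(raw$y_deg)
  raw$eye <- toupper(raw$eye)

  # drop blind-spot rows per eye
  bs <- (raw$eye == "OD" & raw$.x == 15L & abs(raw$.y) == 3L) |
        (raw$eye == "OS" & raw$.x == -15L & abs(raw$.y) == 3L)
  if (any(bs))
    message(sprintf("read_vf_fields: dropped %d blind-spot row(s)", sum(bs)))
  raw <- raw[!bs, , drop = FALSE]

  key <- interaction(raw$subject_id, raw$eye, raw$session_id, raw$stimulus,
                     drop = TRUE, lex.order = TRUE)
  fields <- lapply(split(raw, key), function(grp) {
    loc <- .loc_key(grp$.x, grp$.y)
    if (anyDuplicated(loc))
      stop(sprintf("field %s/%s/%s/%s: duplicate location %s",
                   grp$subject_id[1], grp$eye[1], grp$session_id[1],
                   grp$stimulus[1],
                   paste0("(", sub(":", ", ", loc[duplicated(loc)][1]), ")")),
           call. = FALSE)
    s <- grp$.sens
    names(s) <- loc
    vf_field(grp$subject_id[1], grp$cohort[1], grp$eye[1], grp$session_id[1],
             grp$stimulus[1], as.numeric(grp$age_years[1]), s)
  })
  names(fields) <- NULL
  if (is.function(schema_config$reliability_filter)) {
    keep <- vapply(fields, schema_config$reliability_filter, logical(1))
    if (any(!keep))
      message(sprintf("read_vf_fields: reliability filter dropped %d field(s)",
                      sum(!keep)))
    fields <- fields[keep]
  }
  fields
}

#' Write visual fields to a long-format CSV
#'
#' Emits the same schema [read_vf_fields()] consumes, one row per
#' non-blind-spot location, so that write followed by read round-trips
#' every field exactly.
#'
#' @param fields a list of `vf_field` objects (a single field or a list of
#'   `vf_pair`s is also accepted).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vf_fields <- function(fields, path) {
  if (inherits(fields, "vf_field")) fields <- list(fields)
  fields <- unlist(lapply(fields, function(f) {
    if (inherits(f, "vf_pair")) list(f$field_III, f$field_V) else list(f)
  }), recursive = FALSE)
  tabs <- lapply(fields, function(f) {
    xy <- do.call(rbind, strsplit(names(f$sens), ":", fixed = TRUE))
    data.frame(subject_id = f$subject_id, cohort = f$cohort, eye = f$eye,
               session_id = f$session_id, stimulus = f$stimulus,
               age_years = f$age_years,
               x_deg = as.integer(xy[, 1]), y_deg = as.integer(xy[, 2]),
               sensitivity_db = unname(f$sens))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair same-day size III and size V fields
#'
#' Groups fields by `(subject_id, eye, session_id)` and returns one
#' [vf_pair()] per group containing exactly one size III and one size V
#' field. Fields with no partner are excluded and their count reported via
#' `message()`.
#'
#' @param fields a list of `vf_field` objects.
#' @return A list of `vf_pair` objects.
#' @export
pair_same_day <- function(fields) {
  stopifnot(all(vapply(fields, inherits, logical(1), "vf_field")))
  key <- vapply(fields, function(f)
    paste(f$subject_id, f$eye, f$session_id, sep = "\r"), character(1))
  groups <- split(fields, key)
  orphans <- 0L
  pairs <- list()
  for (grp in groups) {
    stim <- vapply(grp, `[[`, character(1), "stimulus")
    if (sum(stim == "III") > 1L || sum(stim == "V") > 1L)
      stop(sprintf(
        "session %s/%s/%s has multiple fields of one stimulus size: ambiguous pairing",
        grp[[1]]$subject_id, grp[[1]]$eye, grp[[1]]$session_id), call. = FALSE)
    if (any(stim == "III") && any(stim == "V")) {
      pairs[[length(pairs) + 1L]] <-
        vf_pair(grp[[which(stim == "III")]], grp[[which(stim == "V")]])
    } else {
      orphans <- orphans + length(grp)
    }
  }
  if (orphans > 0L)
    message(sprintf("pair_same_day: excluded %d unpartnered field(s)", orphans))
  pairs
}
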