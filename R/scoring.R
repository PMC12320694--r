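# Ordinal scoring of qualitative lymphoscintigraphy reads and the transport
# index (TI). A "read" is one limb's visual assessment, kept as one row of a
# tibble with columns K, D, node_time_min, N, V, collateral:
#   K  lymphatic transport kinetics   0 no delay / 3 mild / 5 marked / 9 missing
#   D  dermal backflow (DBF)          0 normal / 3 partial / 5 diffuse / 9 stop
#   node_time_min  minutes to first appearance of ilio-inguinal nodes
#                  (one of the imaging frames), NA when nodes never appear
#   N  node visualization             0 clear / 3 mild / 5 hardly / 9 none
#   V  main-vessel visualization      0 clear / 3 mild / 5 hardly / 9 none
#   collateral     collateral-flow visualization flag (does not enter the TI)

#' Ordinal score levels and imaging frames
#'
#' `ti_score_levels` are the admissible ordinal grades for the K, D, N and V
#' components; `ti_frames` are the standard acquisition times (minutes after
#' injection) of the whole-body images; `ti_frames_120` is the reduced frame
#' set used for the 120-minute transport index.
#'
#' @format Integer vectors.
#' @export
ti_score_levels <- c(0L, 3L, 5L, 9L)

#' @rdname ti_score_levels
#' @export
ti_frames <- c(15L, 30L, 60L, 120L, 180L, 240L)

#' @rdname ti_score_levels
#' @export
ti_frames_120 <- c(15L, 60L, 120L)

#' Label/score maps for the ordinal components
#'
#' Named list mapping each component's ordinal scores (0/3/5/9) to the visual
#' grades they encode, for CSV import/export of labelled data.
#'
#' @export
ti_score_labels <- list(
  K = c(`0` = "no delay", `3` = "mild delay", `5` = "marked delay", `9` = "missing transport"),
  D = c(`0` = "normal", `3` = "partial", `5` = "diffuse", `9` = "transport stop"),
  N = c(`0` = "clearly visible", `3` = "mildly visible", `5` = "hardly visible", `9` = "no visualization"),
  V = c(`0` = "clearly visible", `3` = "mildly visible", `5` = "hardly visible", `9` = "no visualization")
)

read_cols <- c("K", "D", "node_time_min", "N", "V", "collateral")

#' Validate a tibble of lymphoscintigraphy reads
#'
#' Checks that every ordinal score is one of 0/3/5/9, that numeric node times
#' are members of the frame set, and that the node-time/node-score consistency
#' constraint holds: nodes that never appear (`node_time_min` missing) must
#' carry node score `N = 9`, and vice versa. Violations raise an error naming
#' the offending field and rows; reads are never silently repaired.
#'
#' @param reads Data frame with columns `K`, `D`, `node_time_min`, `N`, `V`,
#'   `collateral` (one row per limb; extra columns such as `patient_id` and
#'   `side` are allowed and preserved).
#' @param frame_set Ordered minutes at which images exist. Numeric node times
#'   must belong to this set.
#' @return The input, invisibly, as a tibble.
#' @export
validate_reads <- function(reads, frame_set = ti_frames) {
  reads <- tibble::as_tibble(reads)
  missing_cols <- setdiff(read_cols, names(reads))
  if (length(missing_cols) > 0) {
    stop("reads are missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_rows <- function(ok) which(!ok)
  for (comp in c("K", "D", "N", "V")) {
    ok <- !is.na(reads[[comp]]) & reads[[comp]] %in% ti_score_levels
    if (any(!ok)) {
      stop(sprintf("invalid %s score (must be one of %s) in row(s): %s",
                   comp, paste(ti_score_levels, collapse = ", "),
                   paste(bad_rows(ok), collapse = ", ")), call. = FALSE)
    }
  }
  t <- reads$node_time_min
  vis <- !is.na(t)
  if (any(vis & t < 0)) {
    stop("negative node_time_min in row(s): ",
         paste(which(vis & t < 0), collapse = ", "), call. = FALSE)
  }
  if (any(vis & !(t %in% frame_set))) {
    stop("node_time_min not an imaging frame (", paste(frame_set, collapse = ", "),
         ") in row(s): ", paste(which(vis & !(t %in% frame_set)), collapse = ", "),
         call. = FALSE)
  }
  if (any(vis & reads$N == 9)) {
    stop("inconsistent read: N = 9 (nodes not visualized) with a numeric node_time_min",
         " in row(s): ", paste(which(vis & reads$N == 9), collapse = ", "), call. = FALSE)
  }
  if (any(!vis & reads$N != 9)) {
    stop("inconsistent read: missing node_time_min (nodes never seen) requires N = 9",
         " in row(s): ", paste(which(!vis & reads$N != 9), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(reads$collateral))) {
    stop("collateral flag must be 0/1 or TRUE/FALSE, not missing", call. = FALSE)
  }
  invisible(reads)
}

#' Time term of the transport index
#'
#' The node-appearance time enters the TI as `0.04 x minutes`, capped at 9 so
#' that no appearance time can score worse than non-visualization (score 9,
#' used when nodes never appear, encoded as `NA`). The cap keeps the TI within
#' its nominal 0.6-45 range for the 240-minute frame (0.04 x 240 = 9.6).
#'
#' @param node_time_min Minutes to first node appearance (vectorized); `NA`
#'   means nodes were never visualized.
#' @param frame_set Admissible imaging frames for numeric times.
#' @return Numeric vector of time-term scores.
#' @examples
#' time_term(15)   # 0.6
#' time_term(NA)   # 9
#' time_term(240)  # capped at 9
#' @export
time_term <- function(node_time_min, frame_set = ti_frames) {
  vis <- !is.na(node_time_min)
  if (any(vis & node_time_min < 0)) stop("node time must be non-negative", call. = FALSE)
  if (any(vis & !(node_time_min %in% frame_set))) {
    stop("node time must be one of the imaging frames: ",
         paste(frame_set, collapse = ", "), call. = FALSE)
  }
  ifelse(vis, pmin(0.04 * node_time_min, 9), 9)
}

#' Transport index of a lymphoscintigraphy read
#'
#' Computes `TI = K + D + 0.04*T + N + V` from the ordinal component scores,
#' with the time term capped at 9 and scored 9 when nodes never appear. The
#' collateral-flow flag does not enter the sum. All arguments are vectorized.
#'
#' @param K,D,N,V Ordinal component scores in \{0, 3, 5, 9\}.
#' @param node_time_min Minutes to first node appearance, `NA` if never seen
#'   (requires `N = 9`).
#' @param frame_set Admissible imaging frames.
#' @return Numeric TI values in \[0.6, 45\].
#' @examples
#' transport_index(K = 3, D = 0, node_time_min = 60, N = 3, V = 0)  # 8.4
#' transport_index(K = 3, D = 5, node_time_min = 60, N = 0, V = 5)  # 15.4
#' @export
transport_index <- function(K, D, node_time_min, N, V, frame_set = ti_frames) {
  df <- tibble::tibble(K = K, D = D, node_time_min = node_time_min,
                       N = N, V = V, collateral = FALSE)
  validate_reads(df, frame_set = frame_set)
  K + D + time_term(node_time_min, frame_set) + N + V
}

#' Censor reads to a reduced imaging window
#'
#' Restricts each read to the images acquired at `retained_frames` (by default
#' 15, 60 and 120 minutes, the frames used for the 120-minute TI). Node times
#' falling on omitted frames before the window's end are snapped forward to
#' the next retained frame — the earliest image on which the nodes are
#' actually seen; nodes first appearing after the last retained frame become
#' non-visualized (`node_time_min = NA`, `N = 9`). Kinetics, dermal backflow
#' and vessel grades are carried over unchanged: they are read from the
#' overall study and the retained frames span the dynamic phase.
#'
#' @param reads Tibble of valid reads (see [validate_reads()]).
#' @param retained_frames Frames kept in the reduced window; must be a
#'   non-empty subset of `frame_set`.
#' @param frame_set Full frame set of the original acquisition.
#' @return A tibble of censored reads with `frame_set` = `retained_frames`.
#' @export
censor_reads <- function(reads, retained_frames = ti_frames_120,
                         frame_set = ti_frames) {
  if (length(retained_frames) == 0) {
    stop("retained_frames must be non-empty", call. = FALSE)
  }
  if (!all(retained_frames %in% frame_set)) {
    stop("retained_frames must be a subset of frame_set", call. = FALSE)
  }
  reads <- validate_reads(reads, frame_set = frame_set)
  retained_frames <- sort(retained_frames)
  t <- reads$node_time_min
  mx <- max(retained_frames)
  vis <- !is.na(t)
  keep <- vis & t %in% retained_frames
  snap <- vis & !keep & t < mx
  lost <- vis & !keep & t >= mx
  if (any(snap)) {
    t[snap] <- vapply(t[snap],
                      function(x) min(retained_frames[retained_frames > x]),
                      numeric(1))
  }
  t[lost] <- NA
  out <- reads
  out$node_time_min <- t
  out$N[lost] <- 9L
  out
}

#' Score reads with the transport index
#'
#' Adds `ti` and `window` columns to a tibble of reads. With `window = 120`
#' the reads are first censored to the 15/60/120-minute frames via
#' [censor_reads()]; with `window = 240` the full acquisition is used.
#'
#' @param reads Tibble of valid reads.
#' @param window Imaging window in minutes, 240 (full) or 120 (reduced).
#' @param frame_set Full frame set of the acquisition.
#' @return The input tibble (uncensored) with `ti` and `window` appended.
#' @export
score_reads <- function(reads, window = 240, frame_set = ti_frames) {
  window <- match.arg(as.character(window), c("240", "120"))
  reads <- validate_reads(reads, frame_set = frame_set)
  scored <- if (window == "120") {
    censor_reads(reads, ti_frames_120, frame_set = frame_set)
  } else {
    reads
  }
  out <- reads
  out$ti <- transport_index(scored$K, scored$D, scored$node_time_min,
                            scored$N, scored$V, frame_set = frame_set)
  out$window <- as.integer(window)
  out
}

#' Dichotomize a read into the six binary interpretation criteria
#'
#' Applies the binary cut-offs used for qualitative assessment: kinetics no or
#' mild delay versus marked delay or missing transport; dermal backflow absent
#' versus any DBF or transport stop; node appearance at 60 minutes or earlier
#' versus later (or never); node and vessel visualization versus none; and
#' collateral flow absent versus present.
#'
#' @param reads Tibble of valid reads.
#' @return Tibble with logical columns `kinetics_delayed`, `dbf_present`,
#'   `node_time_late`, `nodes_not_visualized`, `vessel_not_visualized`,
#'   `collateral_present`, preceded by any `patient_id`/`side` columns present
#'   in the input.
#' @export
binarize_reads <- function(reads) {
  reads <- validate_reads(reads)
  flags <- tibble::tibble(
    kinetics_delayed = reads$K %in% c(5, 9),
    dbf_present = reads$D %in% c(3, 5, 9),
    node_time_late = is.na(reads$node_time_min) | reads$node_time_min > 60,
    nodes_not_visualized = reads$N == 9,
    vessel_not_visualized = reads$V == 9,
    collateral_present = as.logical(reads$collateral)
  )
  id_cols <- intersect(c("patient_id", "side", "reading"), names(reads))
  dplyr::bind_cols(reads[id_cols], flags)
}

#' Enumerate every valid lymphoscintigraphy read
#'
#' Cartesian product of the ordinal grades for K, D, V with the admissible
#' node states: each numeric frame paired with a visible node grade
#' (N in \{0, 3, 5\}), plus the non-visualized state (`node_time_min = NA`,
#' `N = 9`). Used for exhaustive verification of TI range and censoring
#' properties.
#'
#' @param frame_set Imaging frames available for node appearance.
#' @return Tibble of all valid reads (collateral fixed to `FALSE`, which the
#'   TI ignores).
#' @export
enumerate_reads <- function(frame_set = ti_frames) {
  node <- rbind(
    expand.grid(node_time_min = frame_set, N = c(0L, 3L, 5L)),
    data.frame(node_time_min = NA_integer_, N = 9L)
  )
  grid <- expand.grid(K = ti_score_levels, D = ti_score_levels,
                      V = ti_score_levels, node_id = seq_len(nrow(node)))
  out <- tibble::tibble(
    K = grid$K, D = grid$D,
    node_time_min = node$node_time_min[grid$node_id],
    N = node$N[grid$node_id], V = grid$V,
    collateral = FALSE
  )
  validate_reads(out, frame_set = frame_set)
  out
}
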