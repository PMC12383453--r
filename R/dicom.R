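#' @name rtplan_io
#' @title DICOM RTPLAN reading and writing (dynamic-arc subset)
#'
#' @description
#' A minimal, self-contained codec for the RTPLAN subset needed for arc-level
#' QA prediction: BeamSequence with ControlPointSequence (gantry angle,
#' cumulative meterset weight, ASYMX/ASYMY jaw and MLCX leaf positions),
#' BeamLimitingDeviceSequence (leaf position boundaries), and
#' FractionGroupSequence (beam meterset and per-fraction beam dose). Files
#' are written as Explicit VR Little Endian with defined-length sequences;
#' the reader accepts the same encoding. Leaf/jaw positions are written at
#' 0.01 mm precision and meterset weights at 1e-6, the stated round-trip
#' tolerances. The per-arc treatment date is carried in BeamDescription
#' (ISO format) since RTPLAN has no per-beam date attribute; RTPlanDate
#' holds the first arc's date as a fallback.
NULL

# ---- low-level encoding helpers -------------------------------------------

uint16_raw <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
uint32_raw <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                                   x %/% 65536 %% 256, x %/% 16777216 %% 256))

dcm_string <- function(x, pad_null = FALSE) {
  r <- charToRaw(x)
  if (length(r) %% 2 == 1)
    r <- c(r, if (pad_null) as.raw(0) else charToRaw(" "))
  r
}

# one data element, explicit VR little endian
dcm_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  head <- c(uint16_raw(group), uint16_raw(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT"))
    c(head, as.raw(c(0, 0)), uint32_raw(len), value_raw)
  else
    c(head, uint16_raw(len), value_raw)
}

dcm_ds <- function(group, elem, values, digits = 6) {
  s <- paste(vapply(values, function(v) {
    out <- formatC(v, format = "f", digits = digits)
    out <- sub("0+$", "", out); sub("\\.$", "", out)
  }, ""), collapse = "\\")
  dcm_element(group, elem, "DS", dcm_string(s))
}
dcm_is <- function(group, elem, values)
  dcm_element(group, elem, "IS",
              dcm_string(paste(as.integer(values), collapse = "\\")))
dcm_txt <- function(group, elem, vr, s)
  dcm_element(group, elem, vr, dcm_string(s, pad_null = vr == "UI"))
dcm_sq <- function(group, elem, items) {
  body <- do.call(c, lapply(items, function(it)
    c(uint16_raw(0xFFFE), uint16_raw(0xE000), uint32_raw(length(it)), it)))
  if (is.null(body)) body <- raw(0)
  dcm_element(group, elem, "SQ", body)
}

SOP_CLASS_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

new_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0("2.25.", format(as.integer(Sys.time()) %% 1000000000L),
           ".", Sys.getpid() %% 10000L, ".", counter)
  }
})

# ---- writer ----------------------------------------------------------------

#' Write arcs to a DICOM RTPLAN file
#'
#' All arcs in one file must belong to the same patient. Arc invariants are
#' validated before writing.
#'
#' @param arcs list of [arc_beam()] objects (or a single `arc_beam`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(arcs, path) {
  if (inherits(arcs, "arc_beam")) arcs <- list(arcs)
  if (!length(arcs)) stop("no arcs to write")
  for (a in arcs) {
    stopifnot(inherits(a, "arc_beam"))
    bad <- validate_arc(a)
    bad <- bad[bad$type %in% c("crossed_pair", "non_monotone_weight"), ,
               drop = FALSE]
    if (nrow(bad))
      stop("arc ", a$arc_id, " violates invariants: ", bad$type[1],
           " at control point ", bad$control_point[1])
  }
  pid <- unique(vapply(arcs, function(a) a$patient_id, ""))
  if (length(pid) != 1) stop("all arcs in one plan must share patient_id")
  machine <- arcs[[1]]$machine
  bounds <- machine$boundaries

  beam_items <- lapply(seq_along(arcs), function(bi) {
    a <- arcs[[bi]]
    n_cp <- n_control_points(a)
    cp_items <- lapply(seq_len(n_cp), function(k) {
      blds <- list(
        c(dcm_txt(0x300A, 0x00B8, "CS", "ASYMX"),
          dcm_ds(0x300A, 0x011C, a$jaws[k, c("x1", "x2")], digits = 2)),
        c(dcm_txt(0x300A, 0x00B8, "CS", "ASYMY"),
          dcm_ds(0x300A, 0x011C, a$jaws[k, c("y1", "y2")], digits = 2)),
        c(dcm_txt(0x300A, 0x00B8, "CS", "MLCX"),
          dcm_ds(0x300A, 0x011C, c(a$bankA[k, ], a$bankB[k, ]), digits = 2)))
      c(dcm_is(0x300A, 0x0112, k - 1L),
        dcm_ds(0x300A, 0x0134, a$cum_weight[k], digits = 6),
        dcm_ds(0x300A, 0x011E, a$gantry_angle[k], digits = 4),
        dcm_sq(0x300A, 0x011A, blds))
    })
    bld_seq <- list(
      c(dcm_txt(0x300A, 0x00B8, "CS", "ASYMX"),
        dcm_is(0x300A, 0x00BC, 1L)),
      c(dcm_txt(0x300A, 0x00B8, "CS", "ASYMY"),
        dcm_is(0x300A, 0x00BC, 1L)),
      c(dcm_txt(0x300A, 0x00B8, "CS", "MLCX"),
        dcm_is(0x300A, 0x00BC, machine$n_pairs),
        dcm_ds(0x300A, 0x00BE, bounds, digits = 2)))
    c(dcm_is(0x300A, 0x00C0, bi),
      dcm_txt(0x300A, 0x00C2, "LO", a$arc_id),
      dcm_txt(0x300A, 0x00C3, "LO", format(a$treatment_date, "%Y-%m-%d")),
      dcm_txt(0x300A, 0x00C4, "CS", "DYNAMIC"),
      dcm_txt(0x300A, 0x00CE, "CS", "TREATMENT"),
      dcm_sq(0x300A, 0x00B6, bld_seq),
      dcm_ds(0x300A, 0x010E, 1, digits = 6),
      dcm_is(0x300A, 0x0110, n_cp),
      dcm_sq(0x300A, 0x0111, cp_items))
  })

  ref_beam_items <- lapply(seq_along(arcs), function(bi) {
    a <- arcs[[bi]]
    c(dcm_ds(0x300A, 0x0084, a$dose_per_fraction, digits = 4),
      dcm_ds(0x300A, 0x0086, a$total_mu, digits = 4),
      dcm_is(0x300C, 0x0006, bi))
  })
  fg_item <- c(dcm_is(0x300A, 0x0071, 1L),
               dcm_is(0x300A, 0x0078, 1L),
               dcm_sq(0x300C, 0x0004, ref_beam_items))

  sop_uid <- new_uid()
  dataset <- c(
    dcm_txt(0x0008, 0x0016, "UI", SOP_CLASS_RTPLAN),
    dcm_txt(0x0008, 0x0018, "UI", sop_uid),
    dcm_txt(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_txt(0x0010, 0x0020, "LO", pid),
    dcm_txt(0x300A, 0x0002, "LO", "arcqa synthetic plan"),
    dcm_txt(0x300A, 0x0006, "DA",
            format(arcs[[1]]$treatment_date, "%Y%m%d")),
    dcm_sq(0x300A, 0x0070, list(fg_item)),
    dcm_sq(0x300A, 0x00B0, beam_items))

  meta_body <- c(
    dcm_txt(0x0002, 0x0002, "UI", SOP_CLASS_RTPLAN),
    dcm_txt(0x0002, 0x0003, "UI", sop_uid),
    dcm_txt(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_raw(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

# ---- reader ----------------------------------------------------------------

read_uint16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1])
read_uint32 <- function(r, i)
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1]) +
  65536 * as.numeric(r[i + 2]) + 16777216 * as.numeric(r[i + 3])

# parse explicit-VR-LE elements in r[start:end]; returns list keyed by
# "gggg,eeee" with parsed values (repeated tags collected in order)
parse_elements <- function(r, start, end) {
  out <- list()
  i <- start
  while (i <= end - 7) {
    group <- read_uint16(r, i); elem <- read_uint16(r, i + 2)
    vr <- rawToChar(r[(i + 4):(i + 5)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- read_uint32(r, i + 8); body_at <- i + 12
    } else {
      len <- read_uint16(r, i + 6); body_at <- i + 8
    }
    if (len == 4294967295) stop("undefined-length elements are not supported")
    key <- sprintf("%04X,%04X", group, elem)
    body <- if (len > 0) r[body_at:(body_at + len - 1)] else raw(0)
    val <- switch(vr,
      SQ = parse_sequence_items(body),
      DS = if (len) as.numeric(strsplit(trimws(rawToChar(body)),
                                        "\\", fixed = TRUE)[[1]]) else numeric(),
      IS = if (len) as.integer(strsplit(trimws(rawToChar(body)),
                                        "\\", fixed = TRUE)[[1]]) else integer(),
      UL = read_uint32(body, 1),
      trimws(rawToChar(body[body != as.raw(0)])))
    if (is.null(out[[key]])) out[[key]] <- list()
    out[[key]][[length(out[[key]]) + 1L]] <- val
    i <- body_at + len
  }
  out
}

parse_sequence_items <- function(body) {
  items <- list()
  i <- 1
  while (i <= length(body) - 7) {
    if (read_uint16(body, i) != 0xFFFE || read_uint16(body, i + 2) != 0xE000)
      stop("malformed sequence item header")
    len <- read_uint32(body, i + 4)
    items[[length(items) + 1L]] <-
      parse_elements(body, i + 8, i + 7 + len)
    i <- i + 8 + len
  }
  items
}

el1 <- function(parsed, key, default = NULL) {
  v <- parsed[[key]]
  if (is.null(v)) default else v[[1]]
}

#' Read arcs from a DICOM RTPLAN file
#'
#' Returns one [arc_beam()] per dynamic treatment beam. Setup/imaging beams
#' (TreatmentDeliveryType other than TREATMENT, or static beams) are
#' skipped. Cumulative meterset weights are normalized to `[0, 1]`; control
#' points that omit gantry/jaw/MLC positions inherit them from the previous
#' control point.
#'
#' @param path path to an RTPLAN written by [write_rtplan()] (or any
#'   Explicit VR Little Endian RTPLAN with defined-length sequences).
#' @param machine optional [machine_spec()]; by default the leaf widths are
#'   taken from the file's LeafPositionBoundaries and the remaining limits
#'   from [machine_spec()] defaults.
#' @return list of `arc_beam` objects.
#' @export
read_rtplan <- function(path, machine = NULL) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  # skip group 0002 using its group length
  if (read_uint16(r, 133) != 2) stop("missing file meta information")
  meta_len <- read_uint32(r, 141)
  ds_start <- 145 + meta_len
  top <- parse_elements(r, ds_start, length(r))
  if (!identical(el1(top, "0008,0016"), SOP_CLASS_RTPLAN))
    stop("not an RTPLAN SOP class")
  pid <- el1(top, "0010,0020", "UNKNOWN")
  plan_date <- el1(top, "300A,0006")
  plan_date <- if (is.null(plan_date)) as.Date("1970-01-01") else
    as.Date(plan_date, format = "%Y%m%d")

  # beam meterset / dose by referenced beam number
  mu <- list(); bdose <- list()
  fgs <- el1(top, "300A,0070", list())
  if (length(fgs)) {
    for (rb in el1(fgs[[1]], "300C,0004", list())) {
      bn <- as.character(el1(rb, "300C,0006"))
      mu[[bn]] <- el1(rb, "300A,0086")
      bdose[[bn]] <- el1(rb, "300A,0084")
    }
  }

  beams <- top[["300A,00B0"]][[1]]
  if (is.null(beams)) stop("plan has no BeamSequence")
  arcs <- list()
  for (b in beams) {
    bn <- el1(b, "300A,00C0")
    name <- el1(b, "300A,00C2", paste0("beam", bn))
    btype <- el1(b, "300A,00C4", "STATIC")
    dtype <- el1(b, "300A,00CE", "TREATMENT")
    if (!identical(dtype, "TREATMENT") || !identical(btype, "DYNAMIC"))
      next
    bld <- el1(b, "300A,00B6", list())
    bounds <- NULL
    for (d in bld)
      if (identical(el1(d, "300A,00B8"), "MLCX"))
        bounds <- el1(d, "300A,00BE")
    cps <- el1(b, "300A,0111")
    if (is.null(cps))
      stop("unsupported plan: beam ", name, " has no control-point sequence")
    m <- machine
    if (is.null(m)) {
      if (is.null(bounds))
        stop("unsupported plan: beam ", name,
             " has no MLC leaf position boundaries")
      m <- machine_spec(leaf_widths = diff(bounds))
    }
    n_cp <- length(cps)
    cw <- numeric(n_cp); ga <- numeric(n_cp)
    bankA <- matrix(NA_real_, n_cp, m$n_pairs)
    bankB <- matrix(NA_real_, n_cp, m$n_pairs)
    jaws <- matrix(NA_real_, n_cp, 4)
    last_ga <- NA_real_; last_jx <- c(NA, NA); last_jy <- c(NA, NA)
    last_mlc <- NULL
    for (k in seq_len(n_cp)) {
      cp <- cps[[k]]
      cw[k] <- el1(cp, "300A,0134", NA_real_)
      g <- el1(cp, "300A,011E")
      if (!is.null(g)) last_ga <- g
      ga[k] <- last_ga
      for (d in el1(cp, "300A,011A", list())) {
        dev <- el1(d, "300A,00B8"); posn <- el1(d, "300A,011C")
        if (identical(dev, "ASYMX") || identical(dev, "X")) last_jx <- posn
        if (identical(dev, "ASYMY") || identical(dev, "Y")) last_jy <- posn
        if (identical(dev, "MLCX")) last_mlc <- posn
      }
      if (is.null(last_mlc))
        stop("unsupported plan: beam ", name,
             " control point ", k, " has no MLCX positions")
      if (length(last_mlc) != 2 * m$n_pairs)
        stop("beam ", name, ": MLCX position count ", length(last_mlc),
             " does not match ", m$n_pairs, " leaf pairs")
      jaws[k, ] <- c(last_jx, last_jy)
      bankA[k, ] <- last_mlc[seq_len(m$n_pairs)]
      bankB[k, ] <- last_mlc[m$n_pairs + seq_len(m$n_pairs)]
    }
    if (any(is.na(cw)) || any(diff(cw) < -1e-9))
      stop("malformed plan: beam ", name,
           " has a non-monotone cumulative meterset weight")
    final <- el1(b, "300A,010E", cw[n_cp])
    if (final > 0) cw <- cw / final
    cw[1] <- 0; cw[n_cp] <- 1
    bdate <- el1(b, "300A,00C3")
    bdate <- tryCatch(as.Date(bdate), error = function(e) plan_date)
    if (is.null(bdate) || is.na(bdate)) bdate <- plan_date
    arcs[[length(arcs) + 1L]] <- arc_beam(
      arc_id = name, patient_id = pid, treatment_date = bdate,
      cum_weight = cw, gantry_angle = ga, bankA = bankA, bankB = bankB,
      jaws = jaws,
      total_mu = mu[[as.character(bn)]] %||% stop("beam ", name,
        ": no referenced BeamMeterset in FractionGroupSequence"),
      dose_per_fraction = bdose[[as.character(bn)]] %||% 1,
      machine = m)
  }
  arcs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
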