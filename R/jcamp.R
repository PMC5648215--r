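# Minimal JCAMP-DX reader for single-spectrum infrared files.
#
# Supports ##XYDATA=(X++(Y..Y)) with AFFN, SQZ, DIF and DUP ordinate
# encodings, and ##XYPOINTS=(XY..XY) pair lists. Compound (##BLOCKS) files
# and NTUPLES are rejected. Y values are scaled by ##YFACTOR and the X grid
# is reconstructed from ##FIRSTX/##LASTX/##NPOINTS (or taken from the
# per-line X with ##XFACTOR applied).

read_jcamp_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # strip $$ comments
  lines <- sub("\\$\\$.*$", "", lines)

  ldr <- function(name) {
    pat <- paste0("^##", name, "\\s*=")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(pat, "", hit[1], ignore.case = TRUE))
  }
  if (!is.na(ldr("BLOCKS"))) {
    stop("multi-block JCAMP files are not supported: ", path, call. = FALSE)
  }

  title  <- ldr("TITLE")
  yunits <- toupper(ldr("YUNITS"))
  mode <- if (is.na(yunits)) NA_character_
          else if (grepl("TRANSMIT", yunits)) "percent_transmittance"
          else if (grepl("ABSORB", yunits)) "absorbance"
          else NA_character_
  xfactor <- as.numeric(ldr("XFACTOR")); if (is.na(xfactor)) xfactor <- 1
  yfactor <- as.numeric(ldr("YFACTOR")); if (is.na(yfactor)) yfactor <- 1

  xy_start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  pts_start <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  end <- grep("^##END\\s*=?", lines, ignore.case = TRUE)
  if (!length(end)) end <- length(lines) + 1L

  if (length(xy_start)) {
    body <- lines[(xy_start[1] + 1L):(min(end[end > xy_start[1]]) - 1L)]
    body <- body[nzchar(trimws(body))]
    y <- decode_asdf_lines(body, path)
    npoints <- as.numeric(ldr("NPOINTS"))
    firstx <- as.numeric(ldr("FIRSTX")); lastx <- as.numeric(ldr("LASTX"))
    if (!is.na(npoints) && npoints != length(y$y)) {
      stop(sprintf("JCAMP %s: NPOINTS=%d but %d ordinates decoded",
                   path, npoints, length(y$y)), call. = FALSE)
    }
    n <- length(y$y)
    x <- if (!is.na(firstx) && !is.na(lastx) && n > 1) {
      seq(firstx, lastx, length.out = n)
    } else {
      y$x_line_starts * xfactor   # fall back on per-line abscissae
    }
    list(title = title, x = x, y = y$y * yfactor, mode = mode)
  } else if (length(pts_start)) {
    body <- lines[(pts_start[1] + 1L):(min(end[end > pts_start[1]]) - 1L)]
    nums <- as.numeric(unlist(strsplit(paste(body, collapse = " "),
                                       "[,;\\s]+")))
    nums <- nums[!is.na(nums)]
    if (length(nums) %% 2 != 0) {
      stop("JCAMP ", path, ": odd number of values in ##XYPOINTS",
           call. = FALSE)
    }
    x <- nums[seq(1, length(nums), by = 2)] * xfactor
    yv <- nums[seq(2, length(nums), by = 2)] * yfactor
    list(title = title, x = x, y = yv, mode = mode)
  } else {
    stop("JCAMP ", path, ": no ##XYDATA or ##XYPOINTS record", call. = FALSE)
  }
}

# ASDF (ASCII squeezed difference form) ordinate decoding.
# SQZ digits replace the leading digit+sign of an absolute value:
#   @ A..I -> +0 +1..+9 ; a..i -> -1..-9
# DIF digits do the same for a difference from the previous ordinate:
#   % J..R -> +0 +1..+9 ; j..r -> -1..-9
# DUP digits repeat the previous token: S..Z -> 2..9 total, s -> 10? (per
# the standard, S=1 extra .. Z=8 extra, s=9 extra).
decode_asdf_lines <- function(body, path) {
  sqz_pos <- stats::setNames(0:9, c("@", LETTERS[1:9]))
  sqz_neg <- stats::setNames(-(1:9), letters[1:9])
  dif_pos <- stats::setNames(0:9, c("%", LETTERS[10:18]))
  dif_neg <- stats::setNames(-(1:9), letters[10:18])
  dup_chr <- stats::setNames(1:9, c(LETTERS[19:26], "s"))

  ys <- numeric(0)
  x_starts <- numeric(0)
  prev_line_dif <- FALSE

  for (line in body) {
    toks <- regmatches(line, gregexpr(
      "[@%A-Za-z][0-9.]*|[+-]?[0-9]+\\.?[0-9]*|\\?", line))[[1]]
    if (!length(toks)) next
    # first token on each data line is the abscissa (plain AFFN number)
    xv <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(xv)) {
      stop("JCAMP ", path, ": cannot parse line start '", toks[1], "'",
           call. = FALSE)
    }
    x_starts <- c(x_starts, xv)
    toks <- toks[-1]

    line_y <- numeric(0)
    last_was_dif <- FALSE
    last_diff <- NA_real_
    for (tk in toks) {
      lead <- substr(tk, 1, 1)
      rest <- substring(tk, 2)
      if (lead %in% names(dup_chr)) {
        count <- dup_chr[[lead]]
        if (nzchar(rest)) count <- as.numeric(paste0(count, rest))
        if (is.na(last_diff) && !length(line_y) && !length(ys)) {
          stop("JCAMP ", path, ": DUP with no preceding value", call. = FALSE)
        }
        for (r in seq_len(count - 1)) {
          if (last_was_dif) {
            prev <- if (length(line_y)) line_y[length(line_y)] else ys[length(ys)]
            line_y <- c(line_y, prev + last_diff)
          } else {
            prev <- if (length(line_y)) line_y[length(line_y)] else ys[length(ys)]
            line_y <- c(line_y, prev)
          }
        }
        next
      }
      val <- if (lead %in% names(sqz_pos) || lead %in% names(sqz_neg)) {
        sign_digit <- if (lead %in% names(sqz_pos)) sqz_pos[[lead]] else sqz_neg[[lead]]
        num <- as.numeric(paste0(abs(sign_digit), rest))
        is_dif <- FALSE
        if (sign_digit < 0 || lead %in% letters[1:9]) num <- -num
        list(v = num, dif = FALSE)
      } else if (lead %in% names(dif_pos) || lead %in% names(dif_neg)) {
        sign_digit <- if (lead %in% names(dif_pos)) dif_pos[[lead]] else dif_neg[[lead]]
        num <- as.numeric(paste0(abs(sign_digit), rest))
        if (sign_digit < 0 || lead %in% letters[10:18]) num <- -num
        list(v = num, dif = TRUE)
      } else if (tk == "?") {
        list(v = NA_real_, dif = FALSE)
      } else {
        list(v = suppressWarnings(as.numeric(tk)), dif = FALSE)
      }
      if (is.na(val$v) && tk != "?") {
        stop("JCAMP ", path, ": cannot parse token '", tk, "'", call. = FALSE)
      }
      if (val$dif) {
        prev <- if (length(line_y)) line_y[length(line_y)] else ys[length(ys)]
        line_y <- c(line_y, prev + val$v)
        last_was_dif <- TRUE
        last_diff <- val$v
      } else {
        line_y <- c(line_y, val$v)
        last_was_dif <- FALSE
        last_diff <- val$v
      }
    }
    # after a DIF-mode line, the first ordinate of the next line is a check
    # value duplicating the last ordinate of the previous line: verify, drop
    if (prev_line_dif && length(ys) && length(line_y)) {
      if (!isTRUE(all.equal(line_y[1], ys[length(ys)], tolerance = 1e-8))) {
        stop("JCAMP ", path, ": DIF check value mismatch", call. = FALSE)
      }
      line_y <- line_y[-1]
    }
    prev_line_dif <- last_was_dif
    ys <- c(ys, line_y)
  }
  list(y = ys, x_line_starts = x_starts)
}
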