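# Column-name dialects across GenePix scanners: 635/633 nm lasers read the
# Cy5 channel, 532/543 nm the Cy3 channel.
.cy5_wavelengths <- c("635", "633")
.cy3_wavelengths <- c("532", "543")

.sample_vocab <- c("UT", "UC", "ST", "SC")

# Contrast definitions: name, the numerator/denominator samples, and which
# clone library each contrast screens.  ER3 slides (UT vs UC) carry the
# differential-expression signal for both libraries; the two ER2 slide sets
# measure rarity/abundance for one library each.
.contrasts <- data.frame(
  contrast    = c("ER3", "ER2F", "ER2R"),
  numerator   = c("UT", "UT", "UC"),
  denominator = c("UC", "ST", "SC"),
  stringsAsFactors = FALSE
)

.role_vocab <- c("forward_library", "reverse_library", "control_gfp",
                 "control_globin", "control_nptii", "control_its", "blank")

.control_roles <- c("control_gfp", "control_globin", "control_nptii",
                    "control_its")

#' Read an ATF-dialect tab-delimited file (GPR or GAL)
#'
#' GenePix files use the Axon Text File layout: an "ATF" version line, a
#' line giving the number of optional header records and data columns, the
#' optional quoted key=value records, a column-name row, then data rows.
#'
#' @param path file path.
#' @return list with components `header` (character vector of the optional
#'   records, quotes stripped) and `data` (data.frame).
#' @keywords internal
read_atf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, open = "rt", encoding = "latin1")
  on.exit(close(con))
  l1 <- readLines(con, n = 1L)
  if (length(l1) == 0L) stop("empty file: ", path)
  if (!grepl("^ATF", l1)) stop("not an ATF file (missing ATF line): ", path)
  l2 <- readLines(con, n = 1L)
  counts <- suppressWarnings(as.integer(strsplit(l2, "\t")[[1L]]))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stop("malformed ATF count line in ", path)
  n_opt <- counts[1L]
  header <- if (n_opt > 0L) readLines(con, n = n_opt) else character(0)
  header <- gsub("^\"|\"$", "", header)
  dat <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                           quote = "\"", stringsAsFactors = FALSE,
                           comment.char = "")
  if (nrow(dat) == 0L) stop("no data rows in ", path)
  list(header = header, data = dat)
}

.find_col <- function(nms, candidates) {
  hit <- which(nms %in% candidates)
  if (length(hit)) hit[1L] else NA_integer_
}

.need_col <- function(dat, candidates, path) {
  i <- .find_col(names(dat), candidates)
  if (is.na(i))
    stop("missing required column '", candidates[1L], "' in ", path)
  dat[[i]]
}

.num_col <- function(x, name, path) {
  if (is.numeric(x)) return(as.numeric(x))
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !is.na(x) & x != "")
  if (length(bad))
    stop("non-numeric value in column '", name, "' at data row ", bad[1L],
         " of ", path)
  y
}

#' Read a GenePix results (GPR) file
#'
#' Parses one scanned array into a spot table. Foreground/background medians
#' and background SDs are taken per channel; the scanner's own
#' signal-to-noise ratio columns are used when present, otherwise SNR is
#' computed as (foreground median - background median) / background SD.
#'
#' @param path path to a `.gpr` file.
#' @param layout optional list with `blocks`, `rows`, `cols`; if supplied,
#'   the file's grid is validated against it.
#' @return an object of class `array_spots`: a list with `array_id`,
#'   `spots` (data.frame, one row per spot in file order), `channel_names`,
#'   `header`, and `extra` (unrecognised columns, preserved verbatim).
#' @export
read_gpr <- function(path, layout = NULL) {
  atf <- read_atf(path)
  dat <- atf$data
  nms <- names(dat)

  med <- function(prefix, wl) paste0(prefix, wl, " Median")
  fg5 <- .need_col(dat, med("F", .cy5_wavelengths), path)
  bg5 <- .need_col(dat, med("B", .cy5_wavelengths), path)
  fg3 <- .need_col(dat, med("F", .cy3_wavelengths), path)
  bg3 <- .need_col(dat, med("B", .cy3_wavelengths), path)

  spots <- data.frame(
    block = as.integer(.need_col(dat, "Block", path)),
    row   = as.integer(.need_col(dat, "Row", path)),
    col   = as.integer(.need_col(dat, "Column", path)),
    id    = as.character(.need_col(dat, "ID", path)),
    name  = if (!is.na(.find_col(nms, "Name"))) as.character(dat[["Name"]])
            else NA_character_,
    fg_cy5 = .num_col(fg5, "F635 Median", path),
    bg_cy5 = .num_col(bg5, "B635 Median", path),
    fg_cy3 = .num_col(fg3, "F532 Median", path),
    bg_cy3 = .num_col(bg3, "B532 Median", path),
    flag  = as.integer(.need_col(dat, "Flags", path)),
    stringsAsFactors = FALSE
  )

  # Background SDs and SNRs: SNR may substitute for a missing SD column.
  sd5_i  <- .find_col(nms, paste0("B", .cy5_wavelengths, " SD"))
  sd3_i  <- .find_col(nms, paste0("B", .cy3_wavelengths, " SD"))
  snr5_i <- .find_col(nms, paste("SNR", .cy5_wavelengths))
  snr3_i <- .find_col(nms, paste("SNR", .cy3_wavelengths))
  spots$bg_sd_cy5 <- if (!is.na(sd5_i))
    .num_col(dat[[sd5_i]], nms[sd5_i], path) else NA_real_
  spots$bg_sd_cy3 <- if (!is.na(sd3_i))
    .num_col(dat[[sd3_i]], nms[sd3_i], path) else NA_real_
  if (!is.na(snr5_i)) {
    spots$snr_cy5 <- .num_col(dat[[snr5_i]], nms[snr5_i], path)
  } else if (!is.na(sd5_i)) {
    spots$snr_cy5 <- (spots$fg_cy5 - spots$bg_cy5) / spots$bg_sd_cy5
  } else {
    stop("neither an SNR column nor a background SD column present for the ",
         "Cy5 channel in ", path)
  }
  if (!is.na(snr3_i)) {
    spots$snr_cy3 <- .num_col(dat[[snr3_i]], nms[snr3_i], path)
  } else if (!is.na(sd3_i)) {
    spots$snr_cy3 <- (spots$fg_cy3 - spots$bg_cy3) / spots$bg_sd_cy3
  } else {
    stop("neither an SNR column nor a background SD column present for the ",
         "Cy3 channel in ", path)
  }

  bad <- with(spots, !is.finite(fg_cy5) | !is.finite(fg_cy3) |
                !is.finite(bg_cy5) | !is.finite(bg_cy3) |
                fg_cy5 < 0 | fg_cy3 < 0 | bg_cy5 < 0 | bg_cy3 < 0)
  if (any(bad))
    stop("negative or non-finite intensity at data row ", which(bad)[1L],
         " of ", path)

  if (!is.null(layout)) {
    got <- list(blocks = max(spots$block), rows = max(spots$row),
                cols = max(spots$col))
    for (f in c("blocks", "rows", "cols"))
      if (!is.null(layout[[f]]) && layout[[f]] != got[[f]])
        stop("grid mismatch in ", path, ": expected ", layout[[f]], " ", f,
             ", found ", got[[f]])
  }

  known <- c("Block", "Row", "Column", "ID", "Name", "Flags",
             med("F", .cy5_wavelengths), med("B", .cy5_wavelengths),
             med("F", .cy3_wavelengths), med("B", .cy3_wavelengths),
             paste0("B", .cy5_wavelengths, " SD"),
             paste0("B", .cy3_wavelengths, " SD"),
             paste("SNR", .cy5_wavelengths), paste("SNR", .cy3_wavelengths))
  extra <- dat[, setdiff(nms, known), drop = FALSE]

  structure(list(array_id = tools::file_path_sans_ext(basename(path)),
                 spots = spots,
                 channel_names = c(cy3 = "Cy3", cy5 = "Cy5"),
                 header = atf$header, extra = extra),
            class = "array_spots")
}

#' Write a GPR file
#'
#' Writes a spot table in the ATF dialect read back by [read_gpr()]. Used by
#' the synthetic-experiment generator; data rows round-trip byte-identically.
#'
#' @param spots data.frame in the layout of `array_spots$spots`.
#' @param path output path.
#' @param header optional character vector of key=value header records.
#' @export
write_gpr <- function(spots, path, header = character(0)) {
  cols <- c("Block", "Row", "Column", "ID", "Name",
            "F635 Median", "B635 Median", "F532 Median", "B532 Median",
            "B635 SD", "B532 SD", "SNR 635", "SNR 532", "Flags")
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) formatC(x, format = "fg",
                                                 digits = 10)
    else as.character(x)
  }
  tab <- data.frame(
    Block = spots$block, Row = spots$row, Column = spots$col,
    ID = spots$id, Name = if (is.null(spots$name)) spots$id else spots$name,
    `F635 Median` = fmt(spots$fg_cy5), `B635 Median` = fmt(spots$bg_cy5),
    `F532 Median` = fmt(spots$fg_cy3), `B532 Median` = fmt(spots$bg_cy3),
    `B635 SD` = fmt(spots$bg_sd_cy5), `B532 SD` = fmt(spots$bg_sd_cy3),
    `SNR 635` = fmt(spots$snr_cy5), `SNR 532` = fmt(spots$snr_cy3),
    Flags = spots$flag, check.names = FALSE, stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "latin1")
  on.exit(close(con))
  writeLines(c("ATF\t1.0",
               paste(length(header), length(cols), sep = "\t"),
               if (length(header)) paste0("\"", header, "\"")), con)
  writeLines(paste(paste0("\"", cols, "\""), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GenePix array list (GAL) file
#'
#' @param path path to the GAL file.
#' @return data.frame with columns block, row, col, id, name in print order.
#' @export
read_gal <- function(path) {
  atf <- read_atf(path)
  dat <- atf$data
  data.frame(block = as.integer(.need_col(dat, "Block", path)),
             row = as.integer(.need_col(dat, "Row", path)),
             col = as.integer(.need_col(dat, "Column", path)),
             id = as.character(.need_col(dat, "ID", path)),
             name = if (!is.na(.find_col(names(dat), "Name")))
               as.character(dat[["Name"]]) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a GAL file
#' @param gal data.frame as returned by [read_gal()].
#' @param path output path.
#' @param header optional header records.
#' @param annotation optional character vector appended as an
#'   "Annotation" column (the annotated-GAL export).
#' @export
write_gal <- function(gal, path, header = character(0), annotation = NULL) {
  tab <- data.frame(Block = gal$block, Row = gal$row, Column = gal$col,
                    ID = gal$id, Name = gal$name,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(annotation)) tab$Annotation <- annotation
  con <- file(path, open = "wt", encoding = "latin1")
  on.exit(close(con))
  writeLines(c("ATF\t1.0",
               paste(length(header), ncol(tab), sep = "\t"),
               if (length(header)) paste0("\"", header, "\"")), con)
  writeLines(paste(paste0("\"", names(tab), "\""), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the experiment design (Targets + SpotTypes + GAL)
#'
#' The Targets file maps each array to its Cy3 and Cy5 samples (vocabulary
#' UT, UC, ST, SC); each array is assigned to the single contrast its sample
#' pair defines, with dye orientation +1 when the contrast's numerator
#' sample was labelled with Cy5 and -1 for its dye swap. SpotTypes rules
#' (first match wins, `*` wildcards) map clone ids to roles.
#'
#' @param targets_path,spottypes_path,gal_path file paths.
#' @param library_mode one of "both", "forward", "reverse".
#' @return an object of class `ssh_design` with components `targets`
#'   (data.frame: array_id, file, cy3, cy5, contrast, orientation),
#'   `spot_types` (rules data.frame), `gal`, `roles` (role per GAL spot)
#'   and `library_mode`.
#' @export
read_ssh_design <- function(targets_path, spottypes_path, gal_path,
                            library_mode = c("both", "forward", "reverse")) {
  library_mode <- match.arg(library_mode)
  tg <- utils::read.delim(targets_path, stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "latin1")
  nm <- tolower(names(tg))
  pick <- function(key) {
    i <- which(nm %in% key)
    if (!length(i)) stop("Targets file lacks a '", key[1L], "' column")
    as.character(tg[[i[1L]]])
  }
  file <- pick(c("filename", "file"))
  cy3 <- toupper(trimws(pick("cy3")))
  cy5 <- toupper(trimws(pick("cy5")))
  array_id <- tools::file_path_sans_ext(basename(file))
  if (anyDuplicated(array_id))
    stop("duplicate array id in Targets file: ",
         array_id[duplicated(array_id)][1L])
  bad <- setdiff(c(cy3, cy5), .sample_vocab)
  if (length(bad))
    stop("unknown sample label '", bad[1L],
         "' in Targets file (expected UT, UC, ST or SC)")

  contrast <- character(length(file))
  orientation <- integer(length(file))
  for (i in seq_along(file)) {
    hit <- which(apply(.contrasts[, c("numerator", "denominator")], 1L,
                       function(p) setequal(p, c(cy3[i], cy5[i]))))
    if (length(hit) != 1L)
      stop("array ", array_id[i], " (Cy3=", cy3[i], ", Cy5=", cy5[i],
           ") matches no contrast")
    contrast[i] <- .contrasts$contrast[hit]
    orientation[i] <- if (cy5[i] == .contrasts$numerator[hit]) 1L else -1L
  }
  for (ct in unique(contrast)) {
    idx <- contrast == ct
    if (sum(idx) < 2L)
      warning("contrast ", ct, " has fewer than 2 arrays")
    if (length(unique(orientation[idx])) < 2L)
      warning("contrast ", ct, " has no dye swap")
  }

  st <- utils::read.delim(spottypes_path, stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "latin1")
  stn <- tolower(names(st))
  rules <- data.frame(
    spot_type = as.character(st[[which(stn == "spottype")[1L]]]),
    id_pattern = as.character(st[[which(stn == "id")[1L]]]),
    name_pattern = if (any(stn == "name"))
      as.character(st[[which(stn == "name")[1L]]]) else "*",
    stringsAsFactors = FALSE
  )
  rules$role <- .spot_type_role(rules$spot_type)

  gal <- read_gal(gal_path)
  roles <- assign_spot_roles(gal$id, gal$name, rules)

  structure(list(targets = data.frame(array_id = array_id, file = file,
                                      cy3 = cy3, cy5 = cy5,
                                      contrast = contrast,
                                      orientation = orientation,
                                      stringsAsFactors = FALSE),
                 spot_types = rules, gal = gal, roles = roles,
                 library_mode = library_mode),
            class = "ssh_design")
}

# Map free-text SpotType labels onto the internal role vocabulary.
.spot_type_role <- function(spot_type) {
  s <- tolower(spot_type)
  role <- rep(NA_character_, length(s))
  patterns <- c(forward_library = "forward|^f$",
                reverse_library = "reverse|^r$",
                control_gfp = "gfp", control_globin = "globin",
                control_nptii = "npt", control_its = "its",
                blank = "blank|empty|buffer")
  for (k in seq_along(patterns))
    role[is.na(role) & grepl(patterns[k], s)] <- names(patterns)[k]
  if (anyNA(role))
    stop("SpotType label '", spot_type[is.na(role)][1L],
         "' matches no known role")
  role
}

#' Assign a role to every spot from SpotTypes rules
#'
#' First matching rule wins; `*` wildcards are honoured in both the ID and
#' Name patterns. Spots matching no rule get role "blank".
#'
#' @param ids,names character vectors per spot.
#' @param rules rules data.frame from [read_ssh_design()].
#' @return character vector of roles.
#' @export
assign_spot_roles <- function(ids, names, rules) {
  roles <- rep(NA_character_, length(ids))
  if (is.null(names) || all(is.na(names))) names <- ids
  for (r in seq_len(nrow(rules))) {
    todo <- is.na(roles)
    if (!any(todo)) break
    ok <- grepl(utils::glob2rx(rules$id_pattern[r]), ids[todo]) &
      grepl(utils::glob2rx(rules$name_pattern[r]), names[todo])
    roles[todo][ok] <- rules$role[r]
  }
  roles[is.na(roles)] <- "blank"
  roles
}

#' Write a limma-style Targets file
#' @param targets data.frame with columns file, cy3, cy5.
#' @param path output path.
#' @export
write_targets <- function(targets, path) {
  utils::write.table(
    data.frame(FileName = targets$file, Cy3 = targets$cy3,
               Cy5 = targets$cy5, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SpotTypes file
#' @param rules data.frame with columns spot_type, id_pattern, name_pattern.
#' @param path output path.
#' @export
write_spot_types <- function(rules, path) {
  utils::write.table(
    data.frame(SpotType = rules$spot_type, ID = rules$id_pattern,
               Name = rules$name_pattern, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
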