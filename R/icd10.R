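#' Map ICD-10 primary-site codes to analysis cancer groups
#'
#' Groups ICD-10 cancer codes into the ten primary-site categories used
#' throughout the analysis: Breast (C50), Colorectal (C18-C21), Lung
#' (C33-C34), Prostate (C61), Gynaecological (C51-C58), Genitourinary
#' (C60, C62-C68), Skin (C43-C44), Haematological (C81-C96), other
#' gastrointestinal (C15-C17, C22-C26), and Other for everything else
#' (including secondary neoplasms C77-C79 and codes outside chapter C).
#'
#' @param code character vector of ICD-10 codes (e.g. `"C50.9"`, `"C341"`)
#' @return character vector of group labels; unmappable codes return
#'   `"Other"`
#' @examples
#' cancer_group_from_code(c("C50.9", "C34.1", "C16.0", "C61"))
#' @export
cancer_group_from_code <- function(code) {
  letter <- toupper(substr(code, 1, 1))
  num <- suppressWarnings(as.integer(substr(code, 2, 3)))
  out <- rep("Other", length(code))
  ok <- !is.na(num) & letter == "C"
  n <- num[ok]
  grp <- rep("Other", length(n))
  grp[n == 50] <- "Breast"
  grp[n >= 18 & n <= 21] <- "Colorectal"
  grp[n %in% c(33, 34)] <- "Lung"
  grp[n == 61] <- "Prostate"
  grp[n >= 51 & n <= 58] <- "Gynaecological"
  grp[n == 60 | (n >= 62 & n <= 68)] <- "Genitourinary"
  grp[n %in% c(43, 44)] <- "Skin"
  grp[n >= 81 & n <= 96] <- "Haematological"
  grp[(n >= 15 & n <= 17) | (n >= 22 & n <= 26)] <- "OtherGI"
  out[ok] <- grp
  out
}

#' @rdname cancer_group_from_code
#' @format NULL
#' @export
cancer_groups <- c(
  "Breast", "Colorectal", "Genitourinary", "Gynaecological",
  "Haematological", "Lung", "Other", "OtherGI", "Prostate", "Skin"
)

# Is a code a cancer code for cohort purposes? Default prefix set is the
# malignant-neoplasm chapter C00-C97; in-situ (D00-D09) and uncertain
# behaviour (D37-D48) ranges can be switched on.
is_cancer_code <- function(code, include_d_codes = FALSE) {
  letter <- toupper(substr(code, 1, 1))
  num <- suppressWarnings(as.integer(substr(code, 2, 3)))
  hit <- letter == "C" & !is.na(num) & num <= 97
  if (include_d_codes) {
    hit <- hit | (letter == "D" & !is.na(num) & (num <= 9 | (num >= 37 & num <= 48)))
  }
  hit & !is.na(hit)
}

# Secondary-neoplasm (metastasis) codes.
is_metastasis_code <- function(code, prefixes = c("C77", "C78", "C79")) {
  toupper(substr(code, 1, 3)) %in% prefixes
}

# Representative primary-site codes to sample from when simulating claims.
group_code_pool <- list(
  Breast         = c("C50.1", "C50.4", "C50.9"),
  Colorectal     = c("C18.0", "C18.7", "C19", "C20", "C21.0"),
  Genitourinary  = c("C60.9", "C62.9", "C64", "C65", "C67.9", "C68.0"),
  Gynaecological = c("C51.9", "C53.9", "C54.1", "C56"),
  Haematological = c("C81.9", "C83.3", "C85.9", "C90.0", "C91.1", "C92.0"),
  Lung           = c("C33", "C34.1", "C34.3", "C34.9"),
  Other          = c("C01", "C10.9", "C41.9", "C49.9", "C71.9", "C73"),
  OtherGI        = c("C15.9", "C16.0", "C22.0", "C25.9", "C26.0"),
  Prostate       = c("C61"),
  Skin           = c("C43.9", "C44.3", "C44.9")
)
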