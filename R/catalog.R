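#' Clinical sign and symptom catalog
#'
#' The 51 binary clinical signs and symptoms queried from clinical notes by
#' the extraction pipeline. Each catalog entry has a canonical free-text
#' phrase (see [symptom_lexicon()]) used both by the synthetic note generator
#' and by the deterministic mock extractor, which makes note-based extraction
#' exactly testable.
#'
#' @return Character vector of 51 unique symptom names, including
#'   `"suspicion of bacterial infection"`.
#' @export
#' @examples
#' length(symptom_catalog())
symptom_catalog <- function() {
  c(
    "elevated inflammatory markers", "positive influenza test",
    "altered mental status", "dehydration + sweating", "metabolic acidosis",
    "abdominal pain", "ketonuria", "elevated liver enzymes", "ascites",
    "risk factors for lung injury", "urticaria + angioedema", "seizures",
    "history of substance abuse", "hypoxemia", "jaundice",
    "positive biopsy or imaging", "risk factors for thrombosis", "tachypnea",
    "cough + sore throat", "exposure to heat", "elevated BNP",
    "elevated tryptase + histamine", "myalgia + headache", "pulmonary edema",
    "elevated lactate", "elevated glucose", "fever",
    "elevated cardiac enzymes", "positive covid-19 test",
    "hematemesis or melena", "dry mucous membranes",
    "bilateral infiltrates on chest x-ray", "suspicion of bacterial infection",
    "elevated d-dimer", "low urine output", "tachycardia",
    "positive toxicology screen", "nausea + vomiting", "cough + dyspnea",
    "history of fluid loss", "anemia", "elevated lipase",
    "positive blood culture", "exposure to allergens",
    "loss of taste or smell", "ECG changes", "hypotension",
    "organ dysfunction", "chest pain", "weight loss + fatigue", "dyspnea"
  )
}

#' Canonical phrase lexicon
#'
#' One fixed free-text phrase per catalog symptom. The synthetic cohort
#' generator plants these phrases in note text, and the mock extraction
#' backend detects presence by exact (fixed-string) phrase matching, so
#' round-trips are deterministic. Phrases are pairwise non-substring so that
#' one planted phrase can never trigger a different symptom.
#'
#' @return Named character vector; names are catalog symptom names.
#' @export
symptom_lexicon <- function() {
  c(
    "elevated inflammatory markers" = "CRP and procalcitonin markedly elevated",
    "positive influenza test" = "influenza A PCR returned positive",
    "altered mental status" = "acutely confused and disoriented",
    "dehydration + sweating" = "profuse diaphoresis with clinical dehydration",
    "metabolic acidosis" = "anion gap metabolic acidosis on blood gas",
    "abdominal pain" = "severe epigastric abdominal tenderness",
    "ketonuria" = "urinalysis shows large ketones",
    "elevated liver enzymes" = "transaminases AST and ALT elevated",
    "ascites" = "moderate ascites on abdominal exam",
    "risk factors for lung injury" = "recent witnessed aspiration event",
    "urticaria + angioedema" = "diffuse urticarial rash with lip angioedema",
    "seizures" = "witnessed generalized tonic-clonic seizure",
    "history of substance abuse" = "long history of heavy alcohol use",
    "hypoxemia" = "oxygen saturation 84 percent on room air",
    "jaundice" = "scleral icterus and jaundice noted",
    "positive biopsy or imaging" = "mass lesion confirmed on biopsy",
    "risk factors for thrombosis" = "recent long-haul flight and immobilization",
    "tachypnea" = "respiratory rate 32 breaths per minute",
    "cough + sore throat" = "productive cough with severe sore throat",
    "exposure to heat" = "found outdoors in extreme heat",
    "elevated BNP" = "BNP markedly elevated at 1800",
    "elevated tryptase + histamine" = "serum tryptase and histamine elevated",
    "myalgia + headache" = "diffuse myalgias and frontal headache",
    "pulmonary edema" = "pulmonary vascular congestion on chest film",
    "elevated lactate" = "lactate 4.2 mmol per liter",
    "elevated glucose" = "glucose 480 mg per deciliter",
    "fever" = "febrile to 39.4 C",
    "elevated cardiac enzymes" = "troponin elevated and rising",
    "positive covid-19 test" = "SARS-CoV-2 PCR returned detected",
    "hematemesis or melena" = "two episodes of hematemesis with melena",
    "dry mucous membranes" = "mucous membranes notably dry",
    "bilateral infiltrates on chest x-ray" = "bilateral patchy infiltrates on chest radiograph",
    "suspicion of bacterial infection" = "clinical concern for bacterial infection",
    "elevated d-dimer" = "d-dimer elevated above age-adjusted threshold",
    "low urine output" = "urine output below 20 ml per hour",
    "tachycardia" = "heart rate 128 beats per minute",
    "positive toxicology screen" = "urine toxicology screen returned positive",
    "nausea + vomiting" = "persistent nausea with repeated vomiting",
    "cough + dyspnea" = "dry cough with progressive breathlessness",
    "history of fluid loss" = "three days of profuse watery diarrhea",
    "anemia" = "hemoglobin 6.8 grams per deciliter",
    "elevated lipase" = "lipase greater than three times normal",
    "positive blood culture" = "blood cultures growing gram-negative rods",
    "exposure to allergens" = "symptoms began minutes after bee sting",
    "loss of taste or smell" = "new loss of taste and smell",
    "ECG changes" = "ST depression on electrocardiogram",
    "hypotension" = "blood pressure 82 over 48",
    "organ dysfunction" = "rising creatinine with oliguric kidney injury",
    "chest pain" = "crushing substernal chest pressure",
    "weight loss + fatigue" = "unintentional weight loss and profound fatigue",
    "dyspnea" = "dyspnea at rest steadily worsening"
  )
}

#' Differential diagnosis disease set
#'
#' The 19 conditions over which the differential is computed: severe sepsis
#' plus 18 sepsis-mimics (conditions whose ED presentation can resemble
#' sepsis).
#'
#' @return Character vector of 19 disease names; the first is
#'   `"Severe Sepsis"`.
#' @export
disease_set <- function() {
  c(
    "Severe Sepsis", "cardiogenic shock", "pulmonary embolism", "hypovolemia",
    "hypovolemic shock", "cirrhosis", "heart failure exacerbation",
    "alcohol/drug withdrawal", "gastrointestinal hemorrhage", "anaphylaxis",
    "acute respiratory distress syndrome", "influenza", "covid-19",
    "myocardial infarction", "coronary artery disease", "malignancy",
    "pancreatitis", "heat stroke", "diabetic ketoacidosis"
  )
}

#' Default disease-to-symptom map
#'
#' Which catalog symptoms are considered evidence for each disease. The
#' catalog fixes the 51 signs but their per-disease assignment is a curated,
#' editable configuration (standard clinical descriptions), not ground truth;
#' users can supply their own map to [likelihood_table()].
#'
#' Within each disease the first symptoms listed are the most
#' disease-specific; the default likelihood values decay in this order.
#'
#' @return Named list mapping each of the 19 diseases to a character vector
#'   of catalog symptom names.
#' @export
disease_symptom_map <- function() {
  list(
    "Severe Sepsis" = c(
      "suspicion of bacterial infection", "elevated lactate",
      "positive blood culture", "organ dysfunction", "fever", "hypotension",
      "elevated inflammatory markers", "tachycardia", "tachypnea",
      "altered mental status", "low urine output"
    ),
    "cardiogenic shock" = c(
      "pulmonary edema", "elevated cardiac enzymes", "elevated BNP",
      "hypotension", "ECG changes", "low urine output", "tachycardia",
      "chest pain"
    ),
    "pulmonary embolism" = c(
      "elevated d-dimer", "risk factors for thrombosis", "tachypnea",
      "hypoxemia", "tachycardia", "chest pain", "dyspnea"
    ),
    "hypovolemia" = c(
      "history of fluid loss", "dry mucous membranes",
      "dehydration + sweating", "tachycardia", "low urine output"
    ),
    "hypovolemic shock" = c(
      "history of fluid loss", "hypotension", "dry mucous membranes",
      "dehydration + sweating", "tachycardia", "low urine output"
    ),
    "cirrhosis" = c(
      "ascites", "jaundice", "elevated liver enzymes",
      "altered mental status", "anemia"
    ),
    "heart failure exacerbation" = c(
      "elevated BNP", "pulmonary edema", "dyspnea", "tachypnea", "hypoxemia"
    ),
    "alcohol/drug withdrawal" = c(
      "history of substance abuse", "positive toxicology screen", "seizures",
      "altered mental status", "tachycardia"
    ),
    "gastrointestinal hemorrhage" = c(
      "hematemesis or melena", "anemia", "hypotension", "tachycardia"
    ),
    "anaphylaxis" = c(
      "exposure to allergens", "urticaria + angioedema",
      "elevated tryptase + histamine", "hypotension", "dyspnea"
    ),
    "acute respiratory distress syndrome" = c(
      "bilateral infiltrates on chest x-ray", "risk factors for lung injury",
      "hypoxemia", "tachypnea", "dyspnea"
    ),
    "influenza" = c(
      "positive influenza test", "myalgia + headache", "cough + sore throat",
      "fever"
    ),
    "covid-19" = c(
      "positive covid-19 test", "loss of taste or smell", "cough + dyspnea",
      "fever", "hypoxemia"
    ),
    "myocardial infarction" = c(
      "elevated cardiac enzymes", "ECG changes", "chest pain", "dyspnea"
    ),
    "coronary artery disease" = c(
      "chest pain", "ECG changes", "elevated cardiac enzymes"
    ),
    "malignancy" = c(
      "positive biopsy or imaging", "weight loss + fatigue", "anemia"
    ),
    "pancreatitis" = c(
      "elevated lipase", "abdominal pain", "nausea + vomiting"
    ),
    "heat stroke" = c(
      "exposure to heat", "altered mental status", "fever",
      "dry mucous membranes", "tachycardia"
    ),
    "diabetic ketoacidosis" = c(
      "elevated glucose", "ketonuria", "metabolic acidosis",
      "abdominal pain", "nausea + vomiting", "dehydration + sweating"
    )
  )
}
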