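# independent oracles, kept deliberately naive and separate from the
# implementation paths they check

# YLL by explicit double loop over (sex, age group) cells
oracle_yll <- function(deaths, life, open_offset = 2.5) {
  total <- 0
  for (i in seq_len(nrow(deaths))) {
    lo <- deaths$age_low[i]; hi <- deaths$age_high[i]
    mid <- if (is.na(hi)) lo + open_offset else (lo + hi + 1) / 2
    tab <- life[life$sex == deaths$sex[i], ]
    le <- approx(tab$age, tab$ex, xout = mid)$y
    total <- total + deaths$deaths[i] * le
  }
  total
}

# hand-expanded DL random-effects pooled log-RR for exactly 2 or 3 studies
oracle_pooled_theta <- function(theta, se) {
  k <- length(theta)
  stopifnot(k %in% c(2, 3))
  w <- 1 / se^2
  fe <- (if (k == 2) w[1] * theta[1] + w[2] * theta[2]
         else w[1] * theta[1] + w[2] * theta[2] + w[3] * theta[3]) / sum(w)
  q <- sum(w * (theta - fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  sum(ws * theta) / sum(ws)
}

# small hand-built tables reused across burden tests
toy_deaths <- function() {
  mortality_table(sex = c("male", "female"),
                  age_low = c(70, 80), age_high = c(74, 84),
                  deaths = c(100, 50))
}

toy_life <- function() {
  life_table(sex = rep(c("male", "female"), each = 2),
             age = c(72.5, 82.5, 72.5, 82.5),
             ex = c(14.5, 6.0, 16.0, 8.9))
}

# random mortality + life table pair for property tests
random_tables <- function(seed) {
  set.seed(seed)
  grp <- data.frame(age_low = seq(0, 85, 5),
                    age_high = c(seq(4, 84, 5), NA))
  n <- nrow(grp)
  deaths <- mortality_table(sex = rep(c("male", "female"), each = n),
                            age_low = rep(grp$age_low, 2),
                            age_high = rep(grp$age_high, 2),
                            deaths = rpois(2 * n, lambda = 200))
  ages <- seq(0, 95, 5)
  exm <- sort(runif(length(ages), 2, 80), decreasing = TRUE)
  exf <- exm + runif(length(ages), 0, 4)
  life <- life_table(sex = rep(c("male", "female"), each = length(ages)),
                     age = rep(ages, 2), ex = c(exm, sort(exf, decreasing = TRUE)))
  list(deaths = deaths, life = life)
}

# the published Germany-2016 scenario grid (4 doses x 3 cost variants);
# cells marked approx_ok are known off-by-one print artefacts, matched to +-1
printed_grid <- function() {
  df <- read.csv(text = "
dose_iu,cost_variant,serum_increase_nmol_l,rrr,deaths_prevented,savings_keur,cost_keur,net_savings_keur,eur_per_life_year
400,base,20,0.110,25281,1011239,15166,996073,49
400,low20,20,0.110,25281,1011239,12133,999106,39
400,high20,20,0.110,25281,1011239,18199,993040,59
600,base,30,0.130,29877,1195100,17493,1177607,48
600,low20,30,0.130,29877,1195100,13994,1181106,39
600,high20,30,0.130,29877,1195100,20991,1174109,58
800,base,40,0.150,34474,1378962,19819,1359143,47
800,low20,40,0.150,34474,1378962,15855,1363107,38
800,high20,40,0.150,34474,1378962,23783,1355179,57
1000,base,50,0.153,35164,1406541,22146,1384395,52
1000,low20,50,0.153,35164,1406541,17717,1388824,41
1000,high20,50,0.153,35164,1406541,26575,1379966,62
", strip.white = TRUE)
  df
}
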