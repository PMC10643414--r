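Package: fishbloc
Title: Bilateral Oligopoly Simulation of International Fishing-Access Markets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates international markets for fishing access in which a
    small number of coastal states sell, and a small number of distant-water
    fishing nations buy, the right to fish inside Exclusive Economic Zones.
    Sellers and buyers exercise market power by strategically under-reporting
    their biomass and fleet capacity to a clearing mechanism (a bilateral
    oligopoly in the style of Hendricks-McAfee); the package solves the Nash
    equilibrium in reports, calibrates country-level Pella-Tomlinson stocks
    from observed catch, derives access and non-access harvest policy
    functions by grid perturbation, intersects them with growth curves to
    obtain steady-state biomass, and compares coalition (cartel), regional,
    and individual-selling scenarios. A synthetic-data generator produces
    market tables with the statistical structure of the African and Pacific
    access markets so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
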