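# Registry of terminal-electron-acceptor half reactions used by the
# electron ledger.  eeq_per_mol is the electron equivalents per mole of
# compound produced or consumed; electrons/protons describe the written
# half reaction and feed the machine charge-balance check
# (oxidized_charge + protons - electrons == reduced_charge).
couples:
  ferrous_iron:
    oxidized_species: "Fe3+"
    reduced_species: "Fe2+"
    eeq_per_mol: 1
    electrons: 1
    protons: 0
    oxidized_charge: 3
    reduced_charge: 2
    note: "Fe3+ + e- = Fe2+"
  sulfide:
    oxidized_species: "SO4^2-"
    reduced_species: "HS-"
    eeq_per_mol: 8
    electrons: 8
    protons: 9
    oxidized_charge: -2
    reduced_charge: -1
    note: "SO4^2- + 9H+ + 8e- = HS- + 4H2O"
  methane_acetoclastic:
    oxidized_species: "CH3COOH"
    reduced_species: "CH4"
    eeq_per_mol: 8
    electrons: 0
    protons: 0
    oxidized_charge: 0
    reduced_charge: 0
    note: "CH3COOH = CH4 + CO2 (disproportionation; 8 eeq/mol CH4 by convention)"
  methane_hydrogenotrophic:
    oxidized_species: "CO2"
    reduced_species: "CH4"
    eeq_per_mol: 8
    electrons: 8
    protons: 8
    oxidized_charge: 0
    reduced_charge: 0
    note: "CO2 + 8H+ + 8e- = CH4 + 2H2O"
  TeCP:
    oxidized_species: "C6Cl5OH"
    reduced_species: "C6HCl4OH"
    eeq_per_mol: 2
    electrons: 2
    protons: 1
    oxidized_charge: 0
    reduced_charge: -1
    note: "C6Cl5OH + H+ + 2e- = C6HCl4OH + Cl-"
  TCP:
    oxidized_species: "C6Cl5OH"
    reduced_species: "C6H2Cl3OH"
    eeq_per_mol: 4
    electrons: 4
    protons: 2
    oxidized_charge: 0
    reduced_charge: -2
    note: "C6Cl5OH + 2H+ + 4e- = C6H2Cl3OH + 2Cl-"
  DCP:
    oxidized_species: "C6Cl5OH"
    reduced_species: "C6H3Cl2OH"
    eeq_per_mol: 6
    electrons: 6
    protons: 3
    oxidized_charge: 0
    reduced_charge: -3
    note: "C6Cl5OH + 3H+ + 6e- = C6H3Cl2OH + 3Cl- (ladder extension to 3,5-DCP)"
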