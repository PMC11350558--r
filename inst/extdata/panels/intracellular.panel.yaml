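# Intracellular endpoint panel: 14 markers (one viability dye, surface
# lineage markers, and intracellular cytotoxic/regulatory proteins) on
# 300 uL of endpoint blood, after fixation/permeabilization.
#
# The authoritative gate drawings for this panel live in supplementary
# material that is not machine-readable here; every node below is a
# reconstruction from the reported population names and standard murine
# conventions, and is flagged accordingly.
schema_version: 1
panel:
  name: intracellular
  scatter_channels: [FSC, SSC]
  markers:
    - {marker: Viability, channel: VioBlue,        role: viability}
    - {marker: CD3,       channel: VioGreen/BV510, role: surface}
    - {marker: NK1.1,     channel: BV570,          role: surface}
    - {marker: CD25,      channel: BV605,          role: surface}
    - {marker: CD4,       channel: BV650,          role: surface}
    - {marker: GranzymeB, channel: FITC,           role: intracellular}
    - {marker: FOXP3,     channel: PE,             role: intracellular}
    - {marker: CD8,       channel: ECD/PE-Vio615,  role: surface}
    - {marker: TIM3,      channel: PerCP/PC5,      role: surface}
    - {marker: PD1,       channel: PC5.5,          role: surface}
    - {marker: CTLA4,     channel: PC7,            role: intracellular}
    - {marker: Perforin,  channel: APC,            role: intracellular}
    - {marker: CD44,      channel: APC5,           role: surface}
    - {marker: CCR5,      channel: APC7,           role: surface}
gating:
  # This panel carries no CD45; fractions are reported relative to viable
  # intact cells.
  leukocyte_node: Viable
  root:
    name: intact
    conditions:
      - {channel: FSC, relation: positive, threshold: 10000}
      - {channel: SSC, relation: positive, threshold: 1500}
    children:
      - name: Viable
        # Viability dye stains dead cells; live cells are dye-negative.
        conditions:
          - {channel: Viability, relation: negative}
        children:
          - name: Tcells
            reported: true
            conditions:
              - {channel: CD3, relation: positive}
              - {channel: NK1.1, relation: negative}
            children:
              - name: CD4_Tcells
                reported: true
                conditions:
                  - {channel: CD4, relation: positive}
                  - {channel: CD8, relation: negative}
                children:
                  - name: CD4_EffTreg_CCR5
                    # Effector regulatory T cells expressing CCR5
                    # (reconstructed: FOXP3+ CD25+ CD44+ CCR5+).
                    reported: true
                    conditions:
                      - {channel: FOXP3, relation: positive}
                      - {channel: CD25, relation: positive}
                      - {channel: CD44, relation: positive}
                      - {channel: CCR5, relation: positive}
              - name: CD8_Tcells
                reported: true
                conditions:
                  - {channel: CD8, relation: positive}
                  - {channel: CD4, relation: negative}
                children:
                  - name: Cytotoxic_CD8
                    # Cytotoxic phenotype: granzyme B and perforin double
                    # positive.
                    reported: true
                    conditions:
                      - {channel: GranzymeB, relation: positive}
                      - {channel: Perforin, relation: positive}
          - name: NKT
            reported: true
            conditions:
              - {channel: CD3, relation: positive}
              - {channel: NK1.1, relation: positive}
            children:
              - name: NKT_PerfNeg_GzmPos
                reported: true
                conditions:
                  - {channel: Perforin, relation: negative}
                  - {channel: GranzymeB, relation: positive}
          - name: NK
            conditions:
              - {channel: CD3, relation: negative}
              - {channel: NK1.1, relation: positive}
            children:
              - name: NK_Perforin
                reported: true
                conditions:
                  - {channel: Perforin, relation: positive}
              - name: NK_act_PerfPos_GzmNeg
                # Activated (CD25+) perforin+ granzyme-B- NK cells.
                reported: true
                conditions:
                  - {channel: Perforin, relation: positive}
                  - {channel: GranzymeB, relation: negative}
                  - {channel: CD25, relation: positive}
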