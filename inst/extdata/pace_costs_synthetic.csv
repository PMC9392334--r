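arm,strategy_code,school_id,amount
original,staff_session,O01,252.56
original,staff_session,O02,255.43
original,staff_session,O03,258.30
original,staff_session,O04,261.17
original,staff_session,O05,264.04
original,staff_session,O06,266.91
original,staff_session,O07,269.78
original,staff_session,O08,272.65
original,staff_session,O09,275.52
original,staff_session,O10,278.39
original,staff_session,O11,281.26
original,staff_session,O12,284.13
original,staff_session,O13,289.87
original,staff_session,O14,292.74
original,staff_session,O15,295.61
original,staff_session,O16,298.48
original,staff_session,O17,301.35
original,staff_session,O18,304.22
original,staff_session,O19,307.09
original,staff_session,O20,309.96
original,staff_session,O21,312.83
original,staff_session,O22,315.70
original,staff_session,O23,318.57
original,staff_session,O24,321.44
original,champion_training,O01,425.92
original,champion_training,O02,430.76
original,champion_training,O03,435.60
original,champion_training,O04,440.44
original,champion_training,O05,445.28
original,champion_training,O06,450.12
original,champion_training,O07,454.96
original,champion_training,O08,459.80
original,champion_training,O09,464.64
original,champion_training,O10,469.48
original,champion_training,O11,474.32
original,champion_training,O12,479.16
original,champion_training,O13,488.84
original,champion_training,O14,493.68
original,champion_training,O15,498.52
original,champion_training,O16,503.36
original,champion_training,O17,508.20
original,champion_training,O18,513.04
original,champion_training,O19,517.88
original,champion_training,O20,522.72
original,champion_training,O21,527.56
original,champion_training,O22,532.40
original,champion_training,O23,537.24
original,champion_training,O24,542.08
original,ongoing_support,O01,75.68
original,ongoing_support,O02,76.54
original,ongoing_support,O03,77.40
original,ongoing_support,O04,78.26
original,ongoing_support,O05,79.12
original,ongoing_support,O06,79.98
original,ongoing_support,O07,80.84
original,ongoing_support,O08,81.70
original,ongoing_support,O09,82.56
original,ongoing_support,O10,83.42
original,ongoing_support,O11,84.28
original,ongoing_support,O12,85.14
original,ongoing_support,O13,86.86
original,ongoing_support,O14,87.72
original,ongoing_support,O15,88.58
original,ongoing_support,O16,89.44
original,ongoing_support,O17,90.30
original,ongoing_support,O18,91.16
original,ongoing_support,O19,92.02
original,ongoing_support,O20,92.88
original,ongoing_support,O21,93.74
original,ongoing_support,O22,94.60
original,ongoing_support,O23,95.46
original,ongoing_support,O24,96.32
original,equipment_pack,O01,74.80
original,equipment_pack,O02,75.65
original,equipment_pack,O03,76.50
original,equipment_pack,O04,77.35
original,equipment_pack,O05,78.20
original,equipment_pack,O06,79.05
original,equipment_pack,O07,79.90
original,equipment_pack,O08,80.75
original,equipment_pack,O09,81.60
original,equipment_pack,O10,82.45
original,equipment_pack,O11,83.30
original,equipment_pack,O12,84.15
original,equipment_pack,O13,85.85
original,equipment_pack,O14,86.70
original,equipment_pack,O15,87.55
original,equipment_pack,O16,88.40
original,equipment_pack,O17,89.25
original,equipment_pack,O18,90.10
original,equipment_pack,O19,90.95
original,equipment_pack,O20,91.80
original,equipment_pack,O21,92.65
original,equipment_pack,O22,93.50
original,equipment_pack,O23,94.35
original,equipment_pack,O24,95.20
original,salaries_distribution,shared,2767.00
adapted,champion_training,A01,425.92
adapted,champion_training,A02,430.76
adapted,champion_training,A03,435.60
adapted,champion_training,A04,440.44
adapted,champion_training,A05,445.28
adapted,champion_training,A06,450.12
adapted,champion_training,A07,454.96
adapted,champion_training,A08,459.80
adapted,champion_training,A09,464.64
adapted,champion_training,A10,469.48
adapted,champion_training,A11,474.32
adapted,champion_training,A12,479.16
adapted,champion_training,A13,488.84
adapted,champion_training,A14,493.68
adapted,champion_training,A15,498.52
adapted,champion_training,A16,503.36
adapted,champion_training,A17,508.20
adapted,champion_training,A18,513.04
adapted,champion_training,A19,517.88
adapted,champion_training,A20,522.72
adapted,champion_training,A21,527.56
adapted,champion_training,A22,532.40
adapted,champion_training,A23,537.24
adapted,champion_training,A24,542.08
adapted,ongoing_support,A01,75.68
adapted,ongoing_support,A02,76.54
adapted,ongoing_support,A03,77.40
adapted,ongoing_support,A04,78.26
adapted,ongoing_support,A05,79.12
adapted,ongoing_support,A06,79.98
adapted,ongoing_support,A07,80.84
adapted,ongoing_support,A08,81.70
adapted,ongoing_support,A09,82.56
adapted,ongoing_support,A10,83.42
adapted,ongoing_support,A11,84.28
adapted,ongoing_support,A12,85.14
adapted,ongoing_support,A13,86.86
adapted,ongoing_support,A14,87.72
adapted,ongoing_support,A15,88.58
adapted,ongoing_support,A16,89.44
adapted,ongoing_support,A17,90.30
adapted,ongoing_support,A18,91.16
adapted,ongoing_support,A19,92.02
adapted,ongoing_support,A20,92.88
adapted,ongoing_support,A21,93.74
adapted,ongoing_support,A22,94.60
adapted,ongoing_support,A23,95.46
adapted,ongoing_support,A24,96.32
adapted,equipment_pack,A01,74.80
adapted,equipment_pack,A02,75.65
adapted,equipment_pack,A03,76.50
adapted,equipment_pack,A04,77.35
adapted,equipment_pack,A05,78.20
adapted,equipment_pack,A06,79.05
adapted,equipment_pack,A07,79.90
adapted,equipment_pack,A08,80.75
adapted,equipment_pack,A09,81.60
adapted,equipment_pack,A10,82.45
adapted,equipment_pack,A11,83.30
adapted,equipment_pack,A12,84.15
adapted,equipment_pack,A13,85.85
adapted,equipment_pack,A14,86.70
adapted,equipment_pack,A15,87.55
adapted,equipment_pack,A16,88.40
adapted,equipment_pack,A17,89.25
adapted,equipment_pack,A18,90.10
adapted,equipment_pack,A19,90.95
adapted,equipment_pack,A20,91.80
adapted,equipment_pack,A21,92.65
adapted,equipment_pack,A22,93.50
adapted,equipment_pack,A23,94.35
adapted,equipment_pack,A24,95.20
adapted,salaries_distribution,shared,701.00
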