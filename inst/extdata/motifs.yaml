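A2:
- 16111A
- 16223C
- 16290T
- 16319T
- 235G
B2:
- 16189G
- 16217A
- 499T
B4b1:
- 16136A
- 16189G
- 16217A
C1:
- 16223C
- 16298T
- 16325T
- 16327A
D1:
- 16223C
- 16325T
- 16362T
D4h3a:
- 16223C
- 16241T
- 16301T
- 16362T
X2a:
- 16213T
- 16278T
- 153G
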