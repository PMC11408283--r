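compound_id	mol_weight_Da	fingerprint
C1	300	1;2;3;4;5;6;7;8;9;10
C2	50	11;12;13
C3	300	20;21;22;23;24;25;26;27;28;29
C4	300	20;21;22;23;24;25;26;27;28;30
C5	1000	40;41;42
C6	400	50;51;52
C7	500	60;61;62
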