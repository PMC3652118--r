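E,IVSA,PS,NG,PG,ETS,LE,consequent
young,young,few,null,young,no,no,negative
young,young,few,null,young,no,yes,negative
young,young,few,null,young,yes,no,negative
young,young,few,null,young,yes,yes,negative
young,young,many,null,young,no,no,positive
young,young,many,null,young,no,yes,positive
young,young,many,null,young,yes,no,positive
young,young,many,null,young,yes,yes,positive
young,young,unusual,null,young,no,no,positive
young,young,unusual,null,young,no,yes,positive
young,young,unusual,null,young,yes,no,positive
young,young,unusual,null,young,yes,yes,positive
young,young,few,few,adult,no,no,negative
young,young,few,few,adult,no,yes,negative
young,young,few,few,adult,yes,no,negative
young,young,few,few,adult,yes,yes,negative
young,young,many,few,adult,no,no,positive
young,young,many,few,adult,no,yes,positive
young,young,many,few,adult,yes,no,positive
young,young,many,few,adult,yes,yes,positive
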