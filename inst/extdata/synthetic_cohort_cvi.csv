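"eye_id","group","visit","metric","value"
"s01","study","baseline","CVI",75.6
"s02","study","baseline","CVI",78.9
"s03","study","baseline","CVI",71.3
"s04","study","baseline","CVI",79.5
"s05","study","baseline","CVI",71.1
"s06","study","baseline","CVI",74.9
"s07","study","baseline","CVI",66.9
"s08","study","baseline","CVI",62.9
"s09","study","baseline","CVI",74.6
"s10","study","baseline","CVI",78.4
"s11","study","baseline","CVI",73.1
"s12","study","baseline","CVI",69
"s13","study","baseline","CVI",80.9
"s14","study","baseline","CVI",71.4
"s15","study","baseline","CVI",71.3
"s16","study","baseline","CVI",75.8
"s17","study","baseline","CVI",74.8
"s18","study","baseline","CVI",69.5
"s19","study","baseline","CVI",60.5
"s01","study","followup","CVI",72.5
"s02","study","followup","CVI",65.7
"s03","study","followup","CVI",68.1
"s04","study","followup","CVI",71.7
"s05","study","followup","CVI",64.1
"s06","study","followup","CVI",68
"s07","study","followup","CVI",61.6
"s08","study","followup","CVI",56.8
"s09","study","followup","CVI",70.1
"s10","study","followup","CVI",73.7
"s11","study","followup","CVI",69
"s12","study","followup","CVI",65.5
"s13","study","followup","CVI",70.5
"s14","study","followup","CVI",67.6
"s15","study","followup","CVI",62
"s16","study","followup","CVI",71.2
"s17","study","followup","CVI",67.1
"s18","study","followup","CVI",56.7
"s19","study","followup","CVI",54.9
"c01","control","baseline","CVI",67.1
"c02","control","baseline","CVI",69.3
"c03","control","baseline","CVI",67.5
"c04","control","baseline","CVI",67.6
"c05","control","baseline","CVI",65.7
"c06","control","baseline","CVI",67.3
"c07","control","baseline","CVI",64.9
"c08","control","baseline","CVI",69.1
"c09","control","baseline","CVI",69
"c10","control","baseline","CVI",66.3
"c11","control","baseline","CVI",65.7
"c12","control","baseline","CVI",67.4
"c13","control","baseline","CVI",66.6
"c14","control","baseline","CVI",67.1
"c15","control","baseline","CVI",68.8
"c16","control","baseline","CVI",66
"c17","control","baseline","CVI",70.2
"c18","control","baseline","CVI",65.8
"c19","control","baseline","CVI",69
"c01","control","followup","CVI",65.9
"c02","control","followup","CVI",69.1
"c03","control","followup","CVI",67.7
"c04","control","followup","CVI",66.9
"c05","control","followup","CVI",65.9
"c06","control","followup","CVI",66.8
"c07","control","followup","CVI",63.4
"c08","control","followup","CVI",67.8
"c09","control","followup","CVI",68.9
"c10","control","followup","CVI",64.8
"c11","control","followup","CVI",65.2
"c12","control","followup","CVI",67.6
"c13","control","followup","CVI",67.4
"c14","control","followup","CVI",65.8
"c15","control","followup","CVI",67.5
"c16","control","followup","CVI",66
"c17","control","followup","CVI",69.9
"c18","control","followup","CVI",64.9
"c19","control","followup","CVI",69.3
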