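time,phase,fraction
2009-10-18T05:33:00Z,new,0.00
2009-10-26T00:42:00Z,first_quarter,0.50
2009-11-02T19:14:00Z,full,1.00
2009-11-09T15:56:00Z,last_quarter,0.50
2009-11-16T19:14:00Z,new,0.00
2009-11-24T21:39:00Z,first_quarter,0.50
2009-12-02T07:30:00Z,full,1.00
2009-12-09T00:13:00Z,last_quarter,0.50
2009-12-16T12:02:00Z,new,0.00
2009-12-31T19:13:00Z,full,1.00
2010-01-15T07:11:00Z,new,0.00
2010-01-30T06:18:00Z,full,1.00
2010-02-14T02:51:00Z,new,0.00
2010-02-28T16:38:00Z,full,1.00
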