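participant_id,test_name,hand,test_date,metric_name,metric_value,age_years
P00001,e-SDMT,none,2020-01-07T11:52:16,correct_responses,34.41,42.2
P00001,e-SDMT,none,2020-01-14T11:52:16,correct_responses,29.65,42.2
P00001,e-SDMT,none,2020-01-21T11:52:16,correct_responses,36.61,42.2
P00001,e-SDMT,none,2020-01-29T02:44:19,correct_responses,38.33,42.2
P00002,e-SDMT,none,2020-02-13T03:12:02,correct_responses,53.15,48.3
P00002,e-SDMT,none,2020-02-20T03:12:02,correct_responses,49.79,48.3
P00002,e-SDMT,none,2020-03-22T05:54:55,correct_responses,49.04,48.3
P00002,e-SDMT,none,2020-03-29T05:54:55,correct_responses,45.53,48.3
P00002,e-SDMT,none,2020-04-10T09:14:25,correct_responses,50.38,48.3
P00002,e-SDMT,none,2020-04-17T09:14:25,correct_responses,49.69,48.3
P00002,e-SDMT,none,2020-04-24T22:09:31,correct_responses,51.7,48.3
P00002,e-SDMT,none,2020-05-01T22:09:31,correct_responses,55.19,48.3
P00002,e-SDMT,none,2020-05-08T22:09:31,correct_responses,47.45,48.3
P00003,e-SDMT,none,2020-03-14T14:18:35,correct_responses,37.15,91.7
P00003,e-SDMT,none,2020-03-21T14:18:35,correct_responses,42.96,91.7
P00003,e-SDMT,none,2020-03-28T14:18:35,correct_responses,38.63,91.7
P00003,e-SDMT,none,2020-04-04T14:18:35,correct_responses,44.89,91.7
P00003,e-SDMT,none,2020-04-11T14:18:35,correct_responses,47.32,91.7
P00003,e-SDMT,none,2020-04-18T14:18:35,correct_responses,45.4,91.7
P00003,e-SDMT,none,2020-04-25T14:18:35,correct_responses,42.84,91.7
P00003,e-SDMT,none,2020-05-22T21:59:52,correct_responses,48.52,91.7
P00003,e-SDMT,none,2020-05-29T21:59:52,correct_responses,50.03,91.7
P00003,e-SDMT,none,2020-07-13T06:37:05,correct_responses,54.72,91.7
P00003,e-SDMT,none,2020-07-20T06:37:05,correct_responses,51.71,91.7
P00003,e-SDMT,none,2020-07-28T15:23:18,correct_responses,47.96,91.7
P00003,e-SDMT,none,2020-08-04T15:23:18,correct_responses,51.11,91.7
P00003,e-SDMT,none,2020-08-11T15:23:18,correct_responses,53.22,91.7
P00003,e-SDMT,none,2020-08-19T05:19:36,correct_responses,56.07,91.7
P00004,e-SDMT,none,2020-02-23T04:06:44,correct_responses,33.94,42
P00004,e-SDMT,none,2020-03-12T05:32:28,correct_responses,31.88,42
P00004,e-SDMT,none,2020-05-04T16:52:37,correct_responses,36.03,42
P00004,e-SDMT,none,2020-05-13T03:45:28,correct_responses,43,42
P00004,e-SDMT,none,2020-05-25T06:50:33,correct_responses,40.62,42
P00004,e-SDMT,none,2020-06-03T03:16:41,correct_responses,36.42,42
P00004,e-SDMT,none,2020-06-10T03:16:41,correct_responses,41.68,42
P00004,e-SDMT,none,2020-06-19T02:38:50,correct_responses,41.14,42
P00004,e-SDMT,none,2020-08-02T13:10:41,correct_responses,49.94,42
P00005,e-SDMT,none,2020-03-24T17:38:59,correct_responses,39.77,41.7
P00005,e-SDMT,none,2020-04-07T02:16:49,correct_responses,38.74,41.7
P00005,e-SDMT,none,2020-04-18T05:05:03,correct_responses,39.63,41.7
P00005,e-SDMT,none,2020-04-25T05:05:03,correct_responses,41.38,41.7
P00005,e-SDMT,none,2020-05-02T05:05:03,correct_responses,43.65,41.7
P00005,e-SDMT,none,2020-05-09T05:05:03,correct_responses,33.18,41.7
P00005,e-SDMT,none,2020-05-16T05:05:03,correct_responses,39.04,41.7
P00005,e-SDMT,none,2020-05-25T03:23:05,correct_responses,41.3,41.7
P00006,e-SDMT,none,2020-01-10T09:39:49,correct_responses,44.86,53
P00006,e-SDMT,none,2020-01-17T09:39:49,correct_responses,51.68,53
P00006,e-SDMT,none,2020-02-01T04:11:50,correct_responses,42.69,53
P00006,e-SDMT,none,2020-02-08T04:11:50,correct_responses,45.56,53
P00006,e-SDMT,none,2020-02-15T08:58:41,correct_responses,57.02,53
P00006,e-SDMT,none,2020-02-22T08:58:41,correct_responses,48.54,53
P00006,e-SDMT,none,2020-03-10T10:40:20,correct_responses,50.85,53
P00006,e-SDMT,none,2020-03-17T10:40:20,correct_responses,43.98,53
P00006,e-SDMT,none,2020-03-24T10:40:20,correct_responses,55.2,53
P00006,e-SDMT,none,2020-03-31T10:40:20,correct_responses,49.43,53
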